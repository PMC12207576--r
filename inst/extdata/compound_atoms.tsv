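compound	atom_id	element	aromatic	n_h
benzene	C1	C	1	1
benzene	C2	C	1	1
benzene	C3	C	1	1
benzene	C4	C	1	1
benzene	C5	C	1	1
benzene	C6	C	1	1
ethylbenzene	C1	C	1	0
ethylbenzene	C2	C	1	1
ethylbenzene	C3	C	1	1
ethylbenzene	C4	C	1	1
ethylbenzene	C5	C	1	1
ethylbenzene	C6	C	1	1
ethylbenzene	C7	C	0	2
ethylbenzene	C8	C	0	3
naphthalene	C1	C	1	1
naphthalene	C2	C	1	1
naphthalene	C3	C	1	1
naphthalene	C4	C	1	1
naphthalene	C4a	C	1	0
naphthalene	C5	C	1	1
naphthalene	C6	C	1	1
naphthalene	C7	C	1	1
naphthalene	C8	C	1	1
naphthalene	C8a	C	1	0
acetophenone	C1	C	1	0
acetophenone	C2	C	1	1
acetophenone	C3	C	1	1
acetophenone	C4	C	1	1
acetophenone	C5	C	1	1
acetophenone	C6	C	1	1
acetophenone	C7	C	0	0
acetophenone	O1	O	0	0
acetophenone	C8	C	0	3
benzyl_alcohol	C1	C	1	0
benzyl_alcohol	C2	C	1	1
benzyl_alcohol	C3	C	1	1
benzyl_alcohol	C4	C	1	1
benzyl_alcohol	C5	C	1	1
benzyl_alcohol	C6	C	1	1
benzyl_alcohol	C7	C	0	2
benzyl_alcohol	O1	O	0	1
phenol	C1	C	1	0
phenol	C2	C	1	1
phenol	C3	C	1	1
phenol	C4	C	1	1
phenol	C5	C	1	1
phenol	C6	C	1	1
phenol	O1	O	0	1
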