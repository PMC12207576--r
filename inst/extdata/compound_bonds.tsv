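compound	atom1	atom2
benzene	C1	C2
benzene	C2	C3
benzene	C3	C4
benzene	C4	C5
benzene	C5	C6
benzene	C6	C1
ethylbenzene	C1	C2
ethylbenzene	C2	C3
ethylbenzene	C3	C4
ethylbenzene	C4	C5
ethylbenzene	C5	C6
ethylbenzene	C6	C1
ethylbenzene	C1	C7
ethylbenzene	C7	C8
naphthalene	C1	C2
naphthalene	C2	C3
naphthalene	C3	C4
naphthalene	C4	C4a
naphthalene	C4a	C5
naphthalene	C5	C6
naphthalene	C6	C7
naphthalene	C7	C8
naphthalene	C8	C8a
naphthalene	C8a	C1
naphthalene	C4a	C8a
acetophenone	C1	C2
acetophenone	C2	C3
acetophenone	C3	C4
acetophenone	C4	C5
acetophenone	C5	C6
acetophenone	C6	C1
acetophenone	C1	C7
acetophenone	C7	O1
acetophenone	C7	C8
benzyl_alcohol	C1	C2
benzyl_alcohol	C2	C3
benzyl_alcohol	C3	C4
benzyl_alcohol	C4	C5
benzyl_alcohol	C5	C6
benzyl_alcohol	C6	C1
benzyl_alcohol	C1	C7
benzyl_alcohol	C7	O1
phenol	C1	C2
phenol	C2	C3
phenol	C3	C4
phenol	C4	C5
phenol	C5	C6
phenol	C6	C1
phenol	C1	O1
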