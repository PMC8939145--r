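microviridin_leader	leader	PFFARFL
salinispora_core	core	TxxxTxxDxxxxDD
cpr_branch_core	core	TxxxTx(6-10)Dx(1-4)D
chryseoviridin_core	core	TxxxxDxxxTxKxPSDxD[DE]
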