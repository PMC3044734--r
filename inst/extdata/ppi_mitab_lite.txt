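# synthetic MITAB-lite fixture: first two columns are interactor accessions
uniprotkb:P14867	uniprotkb:P27824	psi-mi:"MI:0018"	-
uniprotkb:P28482	uniprotkb:P14867	psi-mi:"MI:0018"	-
uniprotkb:P27824	uniprotkb:P28482	psi-mi:"MI:0007"	-
uniprotkb:P14867	uniprotkb:P14867	psi-mi:"MI:0018"	-
uniprotkb:P27824	uniprotkb:P14867	psi-mi:"MI:0018"	-
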