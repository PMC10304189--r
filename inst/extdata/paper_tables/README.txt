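Experimental and calculated vibrational frequency tables for Finasteride
(FIN), Lamivudine (LAM) and Repaglinide (REP), vendored row-for-row as
printed (cm^-1). *_t1: single-molecule calculation + 0.99-scaled column.
*_t2: central-molecule calculation (scaled single-molecule column repeated
for comparison). *_t3: intercepted-fragment calculation (central-molecule
column repeated for comparison). Note: the REP scaled column and one LAM row
(1041.08 -> 1033.67) are not consistent with the stated 0.99 factor; they
are vendored as printed.
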