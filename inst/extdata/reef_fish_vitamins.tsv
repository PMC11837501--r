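mag_id	diet	B1	B2	B7	B9	B12
H1N1.001	piscivorous	1	1	1	1	1
H1N1.003	piscivorous	0	1	1	1	1
H1N1.005	piscivorous	0	0	1	0	0
H1N1.006	piscivorous	0	0	1	1	1
H1N1.007	piscivorous	1	0	0	1	1
H1N1.009	piscivorous	0	0	1	1	0
H1N1.010	piscivorous	1	0	1	1	1
H1N1.011	piscivorous	0	0	0	0	0
H1N1.012	piscivorous	0	0	1	1	1
H1N1.015	piscivorous	0	0	1	1	0
H1N1.018	piscivorous	0	0	0	0	1
H1N1.021	piscivorous	0	0	0	1	0
H1N1.022	piscivorous	1	1	1	1	0
H1N1.025	piscivorous	0	1	0	1	0
H1N1.026	piscivorous	1	0	1	0	0
H1N1.028	piscivorous	1	0	1	1	0
H1N1.030	piscivorous	1	0	1	1	0
H1N1.033	piscivorous	0	0	0	0	0
T4LTN.001	herbivorous	1	1	1	1	0
T4LTN.002	herbivorous	0	0	0	0	0
T4LTN.003	herbivorous	1	1	1	1	0
T4LTN.004	herbivorous	1	1	1	1	1
T4LTN.005	herbivorous	1	1	1	1	1
T4LTN.006	herbivorous	0	0	1	0	1
T4LTN.007	herbivorous	1	1	1	1	0
T4LTN.009	herbivorous	1	0	1	0	0
T4LTN.010	herbivorous	0	0	0	0	0
T4LTN.011	herbivorous	0	0	0	1	0
T4LTN.012	herbivorous	1	1	1	1	1
T4LTN.014.2	herbivorous	0	0	0	0	0
T4LTN.014.3	herbivorous	0	0	0	0	0
T4LTN.015	herbivorous	0	0	0	0	0
T4LTN.016	herbivorous	1	0	1	1	0
T4LTN.017	herbivorous	0	0	1	0	0
T4LTN.022	herbivorous	1	0	0	0	0
T4LTN.023	herbivorous	1	0	0	0	0
Tr3LTN.002	invertivorous	1	1	1	1	1
Tr3LTN.005	invertivorous	0	1	0	1	1
Tr3LTN.006	invertivorous	1	0	1	1	0
Tr3LTN.008	invertivorous	1	0	1	0	0
Tr3LTN.016	invertivorous	0	0	0	0	0
Tr3LTN.017	invertivorous	0	0	0	0	0
Tr3LTN.026	invertivorous	0	0	0	0	0
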