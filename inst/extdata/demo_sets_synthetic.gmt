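demo_set_alpha	synthetic placeholder set, no biological meaning	G0001	G0003	G0005	G0007	G0009	G0011
demo_set_beta	synthetic placeholder set, no biological meaning	G0002	G0004	G0006	G0008
demo_set_gamma	synthetic placeholder set, no biological meaning	G0010	G0012	G0014	G0016	G0018	G0020	G0022
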