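,probe1,probe2,probe3,probe4,probe5,probe6,probe7,probe8
control,6.323,7.107,8.14,9.563,6.194,9.445,9.58,8.712
case,6.611,7.039,8.099,8.944,6.683,9.051,11.663,8.741
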