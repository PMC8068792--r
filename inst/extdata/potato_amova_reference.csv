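analysis,ms_among,ms_within,phipt_printed,group_sizes
seven_origins,80.296,26.329,0.031,29|42|48|122|60|41|140
dapc_eight_clusters,67.506,26.404,0.026,41|55|85|22|30|83|80|86
subpopulation_2,159.248,21.398,0.290,26|18|8
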