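stage	ph	cod_mg_l	ammonia_mgN_l	nitrite_mgN_l	nitrate_mgN_l
Filtrate	8.1	535	716.0	69.6	20.8
PN-effluent	6.8	405	462.0	424.8	46.2
Anammox-effluent	6.9	350	56.0	28.0	48.2
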