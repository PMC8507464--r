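field_size_cm2,snr2_rate_per_s,k_rate_uGy_s,pka_rate_uGy_m2_s,fom_k_per_uGy,fom_ka_per_uGy_m2
236,770,102,0.98,7.56,784
441,695,82,1.62,8.50,429
658,654,78,2.21,8.40,295
870,542,77,2.74,7.05,198
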