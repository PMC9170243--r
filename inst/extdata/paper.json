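{"l4_grid":24,"v1e_grid":24,"v1i_grid":12,"v4e_grid":24,"v4i_grid":12,"alpha_ffwd_l4":0.05,"alpha_ffwd_v4":0.05,"alpha_rec":0.1,"k_ffwd":50,"k_from_e":40,"k_from_i":10,"j_ee":0.6,"j_ie":2.4,"j_ei":-6,"j_ii":-6,"gamma_l4":20,"ffwd_i_factor":0.4,"ffwd_scale":10,"v_floor":-100,"tau_e":5,"tau_i":8,"taum_e":15,"taum_i":10,"EL":-60,"VT":-50,"Vth":-10,"Vre":-65,"DeltaT_e":2,"DeltaT_i":0.5,"tauref_e":1.5,"tauref_i":0.5,"dt":0.01,"protocol":{"off_ms":300,"on_ms":200,"total_ms":20000,"r_x":5,"rate_dt_ms":2,"n_cycles":40},"rate_ceiling_hz":200,"stimulus":{"column_spacing":0.2,"pixels":25,"sigma":0.2,"lambda":0.6,"phase":0,"tau_n":40,"sigma_n":3.5},"attention":{"gamma_range":[20,23],"mu_i_range":[0,0.5]}}
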