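{"theta":{"baseline_plt_pat":90.5,"mmt_pat":6.1,"rho":0.945,"day1_boost":20.1,"sibling_boost_ratio":2.75,"transfusion_boost":10.6,"atg_alpha":0.01,"atg_kint":0.35,"graft10":72.4,"mmt_gt":7,"gamma":0.19,"ttbm":1.5,"kel":0.353,"hct0":4.22,"tp_median":5.43,"tp_exponent":0.197,"n_transit":3},"iiv_cv":{"baseline_plt_pat":115,"mmt_pat":0,"rho":152.3,"day1_boost":289.7,"sibling_boost_ratio":0,"transfusion_boost":67.9,"atg_alpha":0,"atg_kint":0,"graft10":82.9,"mmt_gt":90.9,"gamma":48.7,"ttbm":0,"kel":0,"hct0":87.1,"tp_median":0,"tp_exponent":0,"n_transit":0},"residual_error":{"prop":0.2,"add":2}}
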