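intervention,age_band,diabetes_averted_k,deaths_averted_k,dfs_gain_yrs,intervention_cost_k,aversion_savings_k,total_savings_k
dpp,55-65,258.78,18.24,0.03,31074700,22048056,-9026644
dpp_ymca,55-65,150.35,4.96,0.02,7677100,12809820,5132720
help_pd,55-65,226.00,22.80,0.03,10039300,19255200,9215900
dpp,45-65,489.06,44.08,0.06,62174800,41667912,-20506888
dpp_ymca,45-65,296.67,26.35,0.03,15361400,25276284,9914884
help_pd,45-65,509.60,58.00,0.06,20088000,43417920,23329920
dpp,35-65,652.84,77.14,0.07,92405900,55621968,-36783932
dpp_ymca,35-65,394.32,44.95,0.05,22829300,33596064,10766764
help_pd,35-65,764.00,107.60,0.08,29853700,65092800,35239100
dpp,25-65,915.80,83.98,0.11,126929900,78026160,-48903740
dpp_ymca,25-65,553.35,62.31,0.06,31358600,47145420,15786820
help_pd,25-65,927.60,130.40,0.11,41007400,79031520,38024120
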