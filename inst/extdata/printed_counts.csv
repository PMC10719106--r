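label,kind,outcome,group,numerator,denominator,printed,ref_a,ref_b
intention_placebo,rate,intention,placebo,1895,2669,71.0,,
intention_health,rate,intention,health,,1063,72.5,,
intention_low_cash,rate,intention,low_cash,,1079,81.7,,
intention_high_cash,rate,intention,high_cash,,1089,78.2,,
intention_cash_headline,rate,intention,cash,1733,2168,81,,
reported_placebo,rate,reported,placebo,672,1850,36.3,,
reported_health,rate,reported,health,,765,38.5,,
reported_low_cash,rate,reported,low_cash,,747,41.9,,
reported_high_cash,rate,reported,high_cash,,739,38.1,,
reported_cash_headline,rate,reported,cash,602,1486,40,,
verified_placebo,rate,verified,placebo,,1544,28.4,,
verified_health,rate,verified,health,,473,21.6,,
verified_low_cash,rate,verified,low_cash,,548,40.7,,
verified_high_cash,rate,verified,high_cash,,510,25.9,,
verified_cash_headline,rate,verified,cash,355,1058,36.6,,
verified_placebo_headline,rate,verified,placebo,439,1544,30.3,,
verified_embedded_control,rate,verified,placebo_village,,,26.8,,
verified_embedded_health,rate,verified,embedded_health,,,22.8,,
verified_embedded_low_cash,rate,verified,embedded_low_cash,,,38.3,,
verified_embedded_high_cash,rate,verified,embedded_high_cash,,,26.3,,
verified_pooled,pooled,verified,all,,,29.1,verified_placebo;verified_health;verified_low_cash;verified_high_cash,
verified_cash_pooled,pooled,verified,cash,,,33.6,verified_low_cash;verified_high_cash,
diff_intention_low_vs_placebo,diff,intention,,,,10.7,intention_low_cash,intention_placebo
diff_intention_low_vs_high,diff,intention,,,,3.5,intention_low_cash,intention_high_cash
diff_verified_low_vs_placebo,diff,verified,,,,12.3,verified_low_cash,verified_placebo
diff_verified_health_vs_placebo,diff,verified,,,,-6.8,verified_health,verified_placebo
diff_verified_embedded_low_spillover,diff,verified,,,,11.5,verified_embedded_low_cash,verified_embedded_control
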