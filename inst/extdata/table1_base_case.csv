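locale,population,strategy,cost,qaly,ly,icer_per_qaly_printed,icer_per_ly_printed
China,ITT,osimertinib,15748,1.6,2.2,4950,3776
China,ITT,platinum-pemetrexed,14085,1.26,1.76,NA,NA
China,CNS,osimertinib,12860,1.12,1.53,3754,2238
China,CNS,platinum-pemetrexed,13365,1.26,1.76,NA,NA
US,ITT,osimertinib,224575,1.75,2.31,159126,135017
US,ITT,platinum-pemetrexed,156987,1.32,1.81,NA,NA
US,CNS,osimertinib,169689,1.2,1.57,-130830,-69025
US,CNS,platinum-pemetrexed,153224,1.32,1.81,NA,NA
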