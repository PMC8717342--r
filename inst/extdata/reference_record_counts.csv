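species,phenology,n_records_raw,n_after_cleaning,n_after_filtering
Arphia conspersa,early,2117,1255,124
Eritettix simplex,early,2441,1830,85
Xanthippus corallipes,early,2452,1746,75
Arphia pseudonietana,late,788,309,66
Opeia obscura,late,659,315,36
Phoetaliotes nebrascensis,late,634,372,41
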