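"patient_id","cycle_checkpoint","category"
"SYN01",3,"PR"
"SYN02",3,"SD"
"SYN03",3,"SD"
"SYN04",3,"SD"
"SYN05",3,"SD"
"SYN06",3,"SD"
"SYN07",3,"SD"
"SYN08",3,"SD"
"SYN09",3,"SD"
"SYN10",3,"SD"
"SYN11",3,"SD"
"SYN12",3,"SD"
"SYN13",3,"SD"
"SYN14",3,"SD"
"SYN15",3,"SD"
"SYN16",3,"SD"
"SYN17",3,"SD"
"SYN18",3,"PD"
"SYN19",3,"PD"
"SYN20",3,"PD"
"SYN21",3,"PD"
"SYN22",3,"PD"
"SYN23",3,"PD"
"SYN24",3,"PD"
"SYN25",3,"PD"
"SYN26",3,"PD"
"SYN27",3,"PD"
"SYN01",6,"PR"
"SYN02",6,"SD"
"SYN03",6,"SD"
"SYN04",6,"SD"
"SYN05",6,"SD"
"SYN06",6,"SD"
"SYN07",6,"SD"
"SYN08",6,"SD"
"SYN09",6,"PD"
"SYN10",6,"PD"
"SYN11",6,"PD"
"SYN12",6,"PD"
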