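infant_id,label,onset_s,offset_s
infant01,rest,0,15
infant01,jaw,16,24
infant01,hand,25,32
infant01,arm,33,38
infant01,foot,39,43
infant01,leg,44,63
infant02,rest,0,46
infant02,hand,47,61
infant02,arm,62,73
infant02,foot,74,82
infant02,leg,83,110
infant03,rest,0,53
infant03,jaw,54,62
infant03,arm,63,73
infant03,leg,74,131
infant04,rest,0,33
infant04,jaw,34,48
infant04,arm,49,55
infant05,rest,0,10
infant05,jaw,11,29
infant05,hand,30,42
infant05,arm,43,53
infant05,foot,54,58
infant05,leg,59,77
infant06,rest,0,36
infant06,jaw,37,47
infant06,hand,48,75
infant06,arm,76,87
infant06,leg,88,109
infant07,rest,0,34
infant07,hand,35,60
infant07,arm,61,89
infant07,leg,90,104
infant08,rest,0,36
infant08,jaw,37,41
infant08,leg,42,46
infant09,rest,0,44
infant09,hand,45,86
infant09,arm,87,96
infant09,leg,97,102
infant10,rest,0,59
infant10,hand,60,87
infant11,rest,0,54
infant11,hand,55,91
infant11,arm,92,119
infant11,foot,120,213
infant11,leg,214,265
infant12,rest,0,40
infant12,arm,41,46
infant12,leg,47,53
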