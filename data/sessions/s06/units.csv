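"unit_id","group","animal","session_id"
"non_compulsive_0001","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0002","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0003","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0004","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0005","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0006","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0007","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0008","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0009","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0010","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0011","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0012","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0013","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0014","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0015","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0016","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0017","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0018","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0019","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0020","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0021","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0022","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0023","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0024","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0025","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0026","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0027","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0028","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0029","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0030","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0031","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0032","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0033","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0034","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0035","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0036","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0037","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0038","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0039","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0040","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0041","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0042","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0043","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0044","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0045","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0046","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0047","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0048","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0049","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0050","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0051","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0052","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0053","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0054","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0055","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0056","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0057","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0058","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0059","non_compulsive","non_compulsive_rat03","s06"
"non_compulsive_0060","non_compulsive","non_compulsive_rat03","s06"
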