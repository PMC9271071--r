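"unit_id","group","animal","session_id"
"compulsive_0001","compulsive","compulsive_rat02","s03"
"compulsive_0002","compulsive","compulsive_rat02","s03"
"compulsive_0003","compulsive","compulsive_rat02","s03"
"compulsive_0004","compulsive","compulsive_rat02","s03"
"compulsive_0005","compulsive","compulsive_rat02","s03"
"compulsive_0006","compulsive","compulsive_rat02","s03"
"compulsive_0007","compulsive","compulsive_rat02","s03"
"compulsive_0008","compulsive","compulsive_rat02","s03"
"compulsive_0009","compulsive","compulsive_rat02","s03"
"compulsive_0010","compulsive","compulsive_rat02","s03"
"compulsive_0011","compulsive","compulsive_rat02","s03"
"compulsive_0012","compulsive","compulsive_rat02","s03"
"compulsive_0013","compulsive","compulsive_rat02","s03"
"compulsive_0014","compulsive","compulsive_rat02","s03"
"compulsive_0015","compulsive","compulsive_rat02","s03"
"compulsive_0016","compulsive","compulsive_rat02","s03"
"compulsive_0017","compulsive","compulsive_rat02","s03"
"compulsive_0018","compulsive","compulsive_rat02","s03"
"compulsive_0019","compulsive","compulsive_rat02","s03"
"compulsive_0020","compulsive","compulsive_rat02","s03"
"compulsive_0021","compulsive","compulsive_rat02","s03"
"compulsive_0022","compulsive","compulsive_rat02","s03"
"compulsive_0023","compulsive","compulsive_rat02","s03"
"compulsive_0024","compulsive","compulsive_rat02","s03"
"compulsive_0025","compulsive","compulsive_rat02","s03"
"compulsive_0026","compulsive","compulsive_rat02","s03"
"compulsive_0027","compulsive","compulsive_rat02","s03"
"compulsive_0028","compulsive","compulsive_rat02","s03"
"compulsive_0029","compulsive","compulsive_rat02","s03"
"compulsive_0030","compulsive","compulsive_rat02","s03"
"compulsive_0031","compulsive","compulsive_rat02","s03"
"compulsive_0032","compulsive","compulsive_rat02","s03"
"compulsive_0033","compulsive","compulsive_rat02","s03"
"compulsive_0034","compulsive","compulsive_rat02","s03"
"compulsive_0035","compulsive","compulsive_rat02","s03"
"compulsive_0036","compulsive","compulsive_rat02","s03"
"compulsive_0037","compulsive","compulsive_rat02","s03"
"compulsive_0038","compulsive","compulsive_rat02","s03"
"compulsive_0039","compulsive","compulsive_rat02","s03"
"compulsive_0040","compulsive","compulsive_rat02","s03"
"compulsive_0041","compulsive","compulsive_rat02","s03"
"compulsive_0042","compulsive","compulsive_rat02","s03"
"compulsive_0043","compulsive","compulsive_rat02","s03"
"compulsive_0044","compulsive","compulsive_rat02","s03"
"compulsive_0045","compulsive","compulsive_rat02","s03"
"compulsive_0046","compulsive","compulsive_rat02","s03"
"compulsive_0047","compulsive","compulsive_rat02","s03"
"compulsive_0048","compulsive","compulsive_rat02","s03"
"compulsive_0049","compulsive","compulsive_rat02","s03"
"compulsive_0050","compulsive","compulsive_rat02","s03"
"compulsive_0051","compulsive","compulsive_rat02","s03"
"compulsive_0052","compulsive","compulsive_rat02","s03"
"compulsive_0053","compulsive","compulsive_rat02","s03"
"compulsive_0054","compulsive","compulsive_rat02","s03"
"compulsive_0055","compulsive","compulsive_rat02","s03"
"compulsive_0056","compulsive","compulsive_rat02","s03"
"compulsive_0057","compulsive","compulsive_rat02","s03"
"compulsive_0058","compulsive","compulsive_rat02","s03"
"compulsive_0059","compulsive","compulsive_rat02","s03"
"compulsive_0060","compulsive","compulsive_rat02","s03"
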