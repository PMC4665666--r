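{
  "version": "1.0",
  "comment": "Published classic accessibility model (E20+E6+FSR+FSHP+AA), fitted by maximum likelihood on a domain-complete 1363-chain X-ray learning set at a 20% RSA threshold, treatment coding with valine baseline, entropies in nats.",
  "descriptors": ["E20", "E6", "FSR", "FSHP", "AA"],
  "baseline": "V",
  "rsa_threshold": 20,
  "cutoff": 0.5,
  "entropy_units": "nats",
  "coefficients": {
    "(Intercept)": -0.528,
    "E20": 0.342,
    "E6": 0.862,
    "FSR": -0.922,
    "FSHP": -1.646,
    "AA:ALA": -0.267,
    "AA:ARG": 0.765,
    "AA:ASN": 0.358,
    "AA:ASP": 0.774,
    "AA:CYS": -1.543,
    "AA:GLN": 0.366,
    "AA:GLU": 0.985,
    "AA:GLY": 0.829,
    "AA:HIS": -0.114,
    "AA:ILE": -0.036,
    "AA:LEU": 0.202,
    "AA:LYS": 1.509,
    "AA:MET": 0.269,
    "AA:PHE": 0.040,
    "AA:PRO": 0.449,
    "AA:SER": -0.166,
    "AA:THR": -0.168,
    "AA:TRP": 0.567,
    "AA:TYR": 0.690
  },
  "se": {
    "(Intercept)": 0.031,
    "E20": 0.012,
    "E6": 0.017,
    "FSR": 0.031,
    "FSHP": 0.030,
    "AA:ALA": 0.034,
    "AA:ARG": 0.034,
    "AA:ASN": 0.035,
    "AA:ASP": 0.034,
    "AA:CYS": 0.052,
    "AA:GLN": 0.036,
    "AA:GLU": 0.034,
    "AA:GLY": 0.038,
    "AA:HIS": 0.038,
    "AA:ILE": 0.027,
    "AA:LEU": 0.023,
    "AA:LYS": 0.036,
    "AA:MET": 0.036,
    "AA:PHE": 0.030,
    "AA:PRO": 0.034,
    "AA:SER": 0.032,
    "AA:THR": 0.032,
    "AA:TRP": 0.041,
    "AA:TYR": 0.029
  },
  "levels": {
    "AA": ["A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y"]
  },
  "converged": true
}
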