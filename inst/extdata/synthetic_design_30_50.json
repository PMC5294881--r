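{"pi0":0.3,"pi1":0.5,"alpha":0.05,"beta":0.1,"n1":22,"r1_futility":6,"r1_efficacy":12,"stages":[{"x1":7,"n2":41,"r":26},{"x1":8,"n2":39,"r":25},{"x1":9,"n2":38,"r":25},{"x1":10,"n2":36,"r":24},{"x1":11,"n2":35,"r":24}]}
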