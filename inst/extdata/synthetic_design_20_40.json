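{"pi0":0.2,"pi1":0.4,"alpha":0.05,"beta":0.2,"n1":18,"r1_futility":3,"r1_efficacy":8,"stages":[{"x1":4,"n2":22,"r":12},{"x1":5,"n2":20,"r":11},{"x1":6,"n2":19,"r":11},{"x1":7,"n2":18,"r":10}]}
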