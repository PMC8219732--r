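# comment: two large inhibitory neurons each suppressing two small targets
BigInhibitsSmall(x, y) {
  x -> y [type = "GABA"]
  x.radius >= 10
  y.radius < 10
}
BigInhibitsSmall(A, C)
BigInhibitsSmall(A, D)
BigInhibitsSmall(B, C)
BigInhibitsSmall(B, D)
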