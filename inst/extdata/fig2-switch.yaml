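# Benign-to-harsh environment switch with an evolvable fusion rate:
# the population first adapts its daughter-cell mass in the benign
# environment, then responds to the harsher environment by evolving
# binary cell fusion instead of larger cells.
kind: simulate
seed: 1
n_cycles: 2000
survival:
  family: vance
params:
  E: 100
  T: 1
  C: 0.6
environments:
  - harshness: 0.5
    label: benign
  - harshness: 2.2
    label: harsh
schedule:
  mode: scheduled
  switch_cycles: [500]
mutation:
  mu: 0.01
  delta_m: 0.02
  delta_alpha: 0.02
initial:
  m: 1.16
  alpha: 0.0
record_every: 1
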