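# Classic short-range lateral inhibition: a cell is inhibited if at least
# one of its six nearest neighbors is Delta-positive. Converges to the
# salt-and-pepper maximal-independent-set pattern.
grid:
  n_rows: 20
  n_cols: 20
  boundary: cylindrical
rule:
  dist: 1
  theta: 1
init:
  seed: 1
run:
  t_max: 500
  equilibrium_window: 50
  record_trajectories: false
output:
  directory: hexnotch-lateral-inhibition
  write_trajectories: false
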