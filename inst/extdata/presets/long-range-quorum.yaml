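# Long-range quorum rule: a cell is inhibited only if at least ten of its
# 18 ring-3 neighbors are Delta-positive. Produces coarser patterns than
# nearest-neighbor lateral inhibition.
grid:
  n_rows: 20
  n_cols: 20
  boundary: cylindrical
rule:
  dist: 3
  theta: 10
init:
  seed: 1
run:
  t_max: 500
  equilibrium_window: 50
  record_trajectories: false
output:
  directory: hexnotch-long-range-quorum
  write_trajectories: false
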