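# Lateral inhibition plus a positional input: a linear Wnt gradient down
# the rows inhibits the transcriptional activity of nuclear NICD. Low-Wnt
# rows (top) differentiate into the salt-and-pepper mosaic; high-Wnt rows
# (bottom) cannot build the Hes repressor, stay uniformly Delta-positive
# and remain undifferentiated.
grid:
  n_rows: 20
  n_cols: 20
  boundary: cylindrical
rule:
  dist: 1
  theta: 1
wnt:
  Wmax: 120
  axis: row
init:
  seed: 1
run:
  t_max: 500
  equilibrium_window: 50
  record_trajectories: false
output:
  directory: hexnotch-wnt-gradient
  write_trajectories: false
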