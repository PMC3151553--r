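# Critical values of the Rao spacing statistic U (degrees) under the
# uniform null, at upper tail probabilities 0.10 / 0.05 / 0.01 / 0.001.
# Obtained by Monte-Carlo simulation of the exact null distribution
# (2e5 replicates per n up to n = 50, 1e5 to n = 200, 5e4 beyond; see
# rao_crit_simulate() to regenerate). Rows are interpolated linearly in n.
.rao_crit <- data.frame(
  n = c(4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 35, 40, 45, 50, 60, 75, 100, 150, 200, 300, 500, 1000),
  c010 = c(168.061, 168.791, 166.206, 165.237, 163.495, 162.652, 161.338, 160.352, 159.438, 158.431, 157.739, 157.028, 156.521, 155.847, 155.205, 154.821, 154.254, 153.983, 153.489, 153.025, 152.676, 152.197, 151.999, 151.631, 151.302, 151.093, 150.871, 149.619, 148.457, 147.775, 147.019, 145.871, 144.709, 143.035, 141.208, 140.017, 138.771, 137.369, 135.985),
  c005 = c(186.706, 183.765, 180.310, 178.051, 175.647, 174.036, 172.292, 170.607, 169.155, 167.726, 166.890, 165.750, 164.854, 164.008, 163.218, 162.424, 161.717, 161.303, 160.621, 160.110, 159.469, 158.901, 158.548, 157.984, 157.573, 157.247, 157.012, 155.177, 153.695, 152.668, 151.615, 150.102, 148.497, 146.398, 143.863, 142.303, 140.575, 138.797, 137.013),
  c001 = c(221.155, 211.984, 207.136, 203.279, 198.214, 195.648, 192.322, 190.317, 188.023, 185.637, 183.799, 182.247, 180.556, 179.643, 178.261, 177.114, 176.028, 175.068, 174.293, 173.200, 172.318, 171.723, 170.925, 170.032, 169.491, 168.965, 168.450, 165.989, 163.491, 161.922, 160.398, 157.979, 155.621, 152.672, 148.876, 146.635, 144.096, 141.400, 138.831),
  c0001 = c(248.062, 246.433, 238.269, 229.875, 223.736, 219.543, 215.101, 212.567, 208.676, 204.722, 203.462, 201.254, 198.610, 196.806, 194.895, 193.107, 192.624, 191.103, 189.453, 187.551, 187.335, 185.838, 184.630, 184.128, 182.661, 182.253, 181.356, 177.594, 174.448, 172.538, 170.431, 167.417, 163.844, 159.814, 154.417, 151.590, 147.911, 144.378, 140.815)
)
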