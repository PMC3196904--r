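# Frozen geometric constants of the beta-solenoid coil builder.
#
# The 16-residue coil cross-section is a closed equilateral polygon of
# C-alpha positions (chord 3.803955 A in 3D with a 0.3 A rise per residue):
# two four-residue beta-strands (TxTA on the +x face, xLxA on the -x face)
# as planar zigzags with a 3.37 A advance and 0.88 A pleat half-amplitude,
# joined by two four-residue turn arcs related by a C2 rotation about the
# coil axis. The five turn edge directions (radians, in-plane) were solved
# once for exact ring closure under shape constraints (face width ~20 A,
# sheet-to-sheet thickness ~10 A, no cross-ring contacts).
#
# Backbone N and C atoms are placed from per-register offsets expressed in
# the intrinsic frame (tangent, bisector, binormal) of the C-alpha trace.
# Strand offsets were solved so strand residues reproduce ideal
# beta-strand torsions (phi ~ -124, psi ~ +127, omega ~ 179, peptide
# C-N 1.33 A); the four turn-register offsets were solved so all turn
# torsions fall in named favourable regions with no steric clashes.
# Registers 9-12 reuse the offsets of 1-4 through the C2 symmetry of the
# coil.

COIL_RISE_DEFAULT <- 4.8
COIL_DZ <- 0.3
COIL_CHORD <- 3.803955
STRAND_DELTA <- 0.882
STRAND_XA <- 3.3
TURN_DIRS <- c(-0.786175265225113, -2.42831590974666, -3.16173543342194, -3.52116426711233, -4.95251815916558)

BB_OFF_STRAND_N <- c(-1.20175858500489, 0.67408049403902, 0.476608634964956)
BB_OFF_STRAND_C <- c(1.26348063073064, 0.738760683944417, 0.428339056853888)
BB_OFF_TURN_N <- rbind(
  c(-1.01002057707955, 0.948151481837463, 0.454567048261648),
  c(-1.20650179143559, 0.800123372213474, 0.17297403417984),
  c(-0.948632254043532, 0.961321324236072, -0.549292415892748),
  c(-1.18116387110946, 0.609323139918785, 0.599450765905939)
)
BB_OFF_TURN_C <- rbind(
  c(1.37577641747636, 0.656159651960472, -0.0481535071934653),
  c(1.20019926826688, 0.888047190766885, -0.310674915985646),
  c(1.44229465762135, 0.482069551273226, -0.11410551403041),
  c(0.996685449774091, 1.08983277815573, -0.380141591865433)
)

BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
BOND_CA_CB <- 1.532

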