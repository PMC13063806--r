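# Tiny in-code fixtures shared across the suite.

# Minimal valid topology of n free atoms (one residue each).
point_topology <- function(n, species = "LIG", subregion = "ligand",
                           radius = 0.17, mass = 12) {
  as_topology(data.frame(
    atom_id = seq_len(n), atom_name = "C", residue_id = seq_len(n),
    species = species, subregion = subregion, element = "C",
    mass_amu = mass, vdw_radius_nm = radius, is_donor = FALSE,
    is_hydrogen = FALSE, is_acceptor = FALSE, donor_of = NA_integer_,
    leaflet_hint = NA))
}

# One-frame trajectory from a coordinate matrix.
one_frame <- function(xyz, box) trajectory(array(xyz, c(nrow(xyz), 3, 1)), box)

# Default small Ld-like and Lo-like configurations.
ld_config <- function(seed = 1)
  build_bilayer_config(bilayer_spec(c(POPC = 40), apl_target = 0.651,
                                    thickness_target = 3.90, seed = seed))
lo_config <- function(seed = 1)
  build_bilayer_config(bilayer_spec(c(PSM = 40, CHOL = 80), apl_target = 0.40,
                                    thickness_target = 4.3, seed = seed))

# Brute-force 2-D MSD oracle on explicit tracks (independent of msd()).
msd_brute <- function(x, y, lag) {
  n <- nrow(x)
  org <- seq_len(n - lag)
  mean((x[org + lag, ] - x[org, ])^2 + (y[org + lag, ] - y[org, ])^2)
}
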