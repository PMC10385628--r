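# In-code fixtures shared across the test files.

atoms_df <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df
}

# a glycine residue with its standard hydrogen set (idealized coordinates)
glycine_model <- function() {
  mol_model(atoms_df(
    id = 1:7,
    element = c("N", "C", "C", "O", "H", "H", "H"),
    name = c("N", "CA", "C", "O", "H", "HA2", "HA3"),
    resname = "GLY", resno = 1L, chain = "A",
    x = c(0, 1.45, 2.00, 3.20, -0.50, 1.80, 1.80),
    y = c(0, 0, 1.40, 1.50, 0.87, -0.50, -0.50),
    z = c(0, 0, 0, 0, 0, 0.85, -0.85)), side = "protein")
}

# arginine guanidinium fragment: CZ with NE/NH1/NH2 and one NH hydrogen
guanidinium_model <- function() {
  mol_model(atoms_df(
    id = 1:5,
    element = c("C", "N", "N", "N", "H"),
    name = c("CZ", "NH1", "NH2", "NE", "HH11"),
    resname = "ARG", resno = 10L, chain = "A",
    x = c(0, 1.33, -0.67, -0.67, 1.90),
    y = c(0, 0, 1.15, -1.15, 0.85),
    z = 0), side = "protein")
}

water_model <- function(pos = c(0, 0, 0)) {
  mol_model(atoms_df(id = 1L, element = "O", name = "O", resname = "HOH",
                     resno = 101L, chain = "A",
                     x = pos[1], y = pos[2], z = pos[3]), side = "protein")
}

# n-atom model at given positions, all carbon, typed
carbon_model <- function(xyz, side = "a", chain = "A", id0 = 0L) {
  xyz <- matrix(xyz, ncol = 3)
  mol_model(atoms_df(id = id0 + seq_len(nrow(xyz)), element = "C",
                     name = "C", resname = "FIX",
                     resno = seq_len(nrow(xyz)), chain = chain,
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                     type = "C"), side = side)
}

rotation_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

rotate_model <- function(model, R, shift = c(0, 0, 0)) {
  contactzones:::set_coords(model, sweep(coords(model) %*% t(R), 2, shift, `+`))
}
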