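# Shared fixtures and an independent brute-force oracle for the cell
# free energy.

worked_oxygen <- function() {
  list(couple = preset_couple("oxygen"),
       red = compartment(c(O2 = 1e-9), pH = 7),
       ox = compartment(c(O2 = 3e-4), pH = 7))
}

# Brute-force free energy: expand the overall reaction
#   a XHn,red + p H+_ox + b X_ox -> a XHn,ox + p H+_red + b X_red
# term by term as (activity, exponent) pairs and accumulate the quotient in
# a loop -- structurally independent of the package's vectorized log-space
# path. Water activity is 1; a proton-as-substrate couple (X == "H+")
# contributes only through the p exponent.
oracle_delta_g <- function(couple, red, ox, distance_mm, params) {
  act <- function(species, comp) {
    if (species == "H2O" || species == "H+") return(1)
    comp$concentrations[[species]]
  }
  h <- function(comp) 10^(-comp$pH)
  terms <- list(  # products positive exponent, substrates negative
    list(act(couple$reduced, ox), couple$reduced_coef),
    list(h(red), couple$n_protons),
    list(act(couple$oxidized, red), couple$oxidized_coef),
    list(act(couple$reduced, red), -couple$reduced_coef),
    list(h(ox), -couple$n_protons),
    list(act(couple$oxidized, ox), -couple$oxidized_coef))
  q <- 1
  for (t in terms) q <- q * t[[1]]^t[[2]]
  8.314 * params$temperature_K * log(q) +
    couple$n_electrons * 96485.3 * params$loss_V_per_mm * distance_mm
}

random_couple <- function() {
  redox_couple(name = "rnd",
               n_electrons = sample(1:8, 1),
               n_protons = sample(0:8, 1),
               standard_potential_V = stats::runif(1, -1, 1),
               oxidized = "X", reduced = "XH",
               oxidized_coef = sample(1:3, 1),
               reduced_coef = sample(1:3, 1))
}

random_compartment <- function() {
  compartment(c(X = 10^stats::runif(1, -9, -1),
                XH = 10^stats::runif(1, -9, -1)),
              pH = stats::runif(1, 4, 10))
}
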