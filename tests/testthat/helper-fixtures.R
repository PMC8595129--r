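# Shared fixtures: the default oligonucleotide drug profile, the monkey
# sampling schedule, and a random-model generator for property tests.

default_drug <- function() {
  physchem_profile(6044.4, "polyanion", logp = -2, fup = 0.02,
                   blood_plasma_ratio = 1)
}

monkey_schedule <- function() c(0.08, 0.17, 0.33, 0.5, 0.75, 1, 1.5, 2, 4, 6)

default_kps <- function() predict_kps(default_drug())

# random but valid whole-body model (lognormal Kps, uniform CL)
random_model <- function(seed, species = "monkey", cl_range = c(0.1, 2)) {
  set.seed(seed)
  phys <- load_physiology(species)
  kps <- setNames(exp(stats::rnorm(nrow(phys$tissues), 0, 1)),
                  phys$tissues$tissue)
  build_model(phys, kps, stats::runif(1, cl_range[1], cl_range[2]))
}

# minimal physiology object for Vss arithmetic checks
toy_physiology <- function(plasma_volume, volumes) {
  structure(list(
    species = "toy", body_weight = sum(volumes) + plasma_volume,
    cardiac_output = 1, hematocrit = 0.45,
    blood_volume = plasma_volume / 0.55,
    plasma_volume = plasma_volume,
    arterial_volume = 0.1, venous_volume = 0.2,
    tissues = data.frame(tissue = names(volumes), volume_L = unname(volumes),
                         flow_L_per_h = 1)
  ), class = "physiology_spec")
}
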