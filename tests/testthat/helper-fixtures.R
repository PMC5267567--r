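# builders shared across test files

# minimal valid dataset row; override any field
make_record <- function(species = "A", family = "famX",
                        suborder = "Cryptodira", population_id = "p1",
                        male_mass_g = 100, female_mass_g = 120,
                        male_scl_cm = NA_real_, female_scl_cm = NA_real_,
                        basis = "mean", captive = FALSE,
                        source_id = "s1") {
  data.frame(species = species, family = family, suborder = suborder,
             population_id = population_id, male_mass_g = male_mass_g,
             female_mass_g = female_mass_g, male_scl_cm = male_scl_cm,
             female_scl_cm = female_scl_cm, basis = basis,
             captive = captive, source_id = source_id)
}

# dataset of one-record species with chosen mass pairs
make_species_dataset <- function(male, female, species = NULL,
                                 family = "famX") {
  n <- length(male)
  if (is.null(species)) species <- sprintf("sp_%03d", seq_len(n))
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_record(species = species[i], family = family,
                population_id = "p1",
                male_mass_g = male[i], female_mass_g = female[i])
  }))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "ssdallometry")
}

balanced_tree_text <- function() {
  "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);"
}
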