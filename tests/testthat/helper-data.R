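# Small in-code fixtures shared across test files.

make_design <- function(conditions = c("Control", "LPS"), layers = "EC",
                        n_animals = 2) {
  do.call(rbind, lapply(conditions, function(cond) {
    off <- if (cond == "Control") 0 else n_animals
    do.call(rbind, lapply(layers, function(ly) {
      a <- seq_len(n_animals) + off
      data.frame(sample_id = sprintf("%s_%s_a%d", ly, cond, a),
                 condition = cond, layer = ly,
                 animal_id = sprintf("a%d", a), stringsAsFactors = FALSE)
    }))
  }))
}

make_psm <- function(sample_id, peptide, modifications = "", proteins,
                     spectral_count = 1L) {
  data.frame(sample_id = sample_id, peptide = peptide,
             modifications = modifications, proteins = proteins,
             spectral_count = as.integer(spectral_count),
             stringsAsFactors = FALSE)
}

# a two-protein toy database with known digestion structure
toy_proteins <- function() {
  data.frame(
    accession = c("P1", "P2"),
    description = c("toy protein one", "toy protein two"),
    # P1: MAKRLSTKPE -> MAK | R | LSTKPE (KP blocks cleavage at K8)
    sequence = c("MAKRLSTKPE", "MSSTYKAAAARGGWK"),
    stringsAsFactors = FALSE
  )
}

small_sim <- function(seed = 42, n_proteins = 40, layers = "EC",
                      conditions = c("Control", "LPS"), ...) {
  cfg <- synthetic_config(n_proteins = n_proteins, layers = layers,
                          conditions = conditions, seed = seed, ...)
  generate_psm_tables(cfg)
}
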