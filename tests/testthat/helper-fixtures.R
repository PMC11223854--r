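# Deterministic small-valued 20 x 36 feature table: fast to train with and
# fully controlled, independent of the shipped default.
tiny_feature_table <- function() {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  vals <- outer(seq_along(aa), seq_len(36),
                function(r, j) sin(r * 0.7 + j * 0.3) + (r * j %% 7) / 10)
  df <- data.frame(residue = aa, vals)
  colnames(df)[-1] <- paste0("f", seq_len(36))
  as_feature_table(df, provenance = "test fixture")
}

tiny_config <- function() {
  network_config(n_bidirectional_layers = 1L, n_dense_layers = 2L,
                 dropout = 0, neurons_per_layer = c(8L, 8L, 8L),
                 batch_size = 16L, learning_rate = 1e-2)
}

published_config <- function() network_config()

# A small trained ensemble shared across test files (trained once per run).
cached_env <- new.env(parent = emptyenv())

small_trained_ensemble <- function() {
  if (is.null(cached_env$ensemble)) {
    dat <- gen_hexapeptides(150, 0.4, noise = 0, seed = 42)
    cached_env$train_data <- dat
    cached_env$ensemble <- train_crossval(
      dat, tiny_config(), k = 5, seed = 42, max_epochs = 20)
  }
  cached_env$ensemble
}

random_hexpeptide <- function(n = 1) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i) {
    paste(sample(aa, 6, replace = TRUE), collapse = "")
  }, character(1))
}

random_protein <- function(len) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}
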