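# fixture builders shared across test files; everything is generated in code

# random binary table with k uniformly assigned classes
random_ds <- function(n = 50, u = 8, k = 3, seed = 1) {
  hfsa:::with_seed(seed, {
    m <- matrix(as.integer(stats::runif(n * u) < 0.5), n, u)
    labels <- sample(LETTERS[seq_len(k)], n, replace = TRUE)
    # ensure every class is present at least twice (when n allows)
    forced <- rep(LETTERS[seq_len(k)], each = 2)
    labels[seq_len(min(n, length(forced)))] <- forced[seq_len(min(n, length(forced)))]
    symptom_dataset(m, labels, paste0("f", seq_len(u)))
  })
}

# noiseless limit: characteristic symptoms always on, no background noise
noiseless_ds <- function(n_diseases = 3, n_features = 9,
                         informative = 2, cases = 10, seed = 1) {
  generate_symptom_data(generator_config(
    n_diseases = n_diseases, n_features = n_features,
    informative_per_disease = informative, p_on = 1, p_noise = 0,
    cases_per_disease = cases, seed = seed))
}

# small noisy benchmark with ground truth, cheap enough for unit tests
small_benchmark <- function(seed = 1, n_diseases = 5, n_features = 25,
                            informative = 3, cases = 30,
                            p_on = 0.9, p_noise = 0.05) {
  generate_symptom_data(generator_config(
    n_diseases = n_diseases, n_features = n_features,
    informative_per_disease = informative, p_on = p_on, p_noise = p_noise,
    cases_per_disease = cases, seed = seed))
}

# a 4-row, 3-symptom CSV written to a temp file
tiny_csv <- function(dir = tempdir()) {
  path <- file.path(dir, "tiny.csv")
  writeLines(c("s1,s2,s3,prognosis",
               "1,0,1,flu",
               "0,1,0,flu",
               "1,1,1,cold",
               "0,0,0,cold"), path)
  path
}
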