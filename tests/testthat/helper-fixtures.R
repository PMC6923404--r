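# Shared fixtures: everything is generated in code, nothing read from disk.

# Small synthetic experiment used by several preprocessing tests.
tiny_experiment <- function(n_events = 1000, seed = 7, ...) {
  truth <- default_truth(n_events = n_events, seed = seed, ...)
  sim <- simulate_experiment(truth)
  scheme <- default_barcode_scheme(vapply(truth$samples, `[[`, "",
                                          "sample_id"))
  list(truth = truth, sim = sim, scheme = scheme)
}

# A bare event table with explicit values: one marker, one barcode, beads,
# DNA, event length and time, for handcrafted gating/normalization cases.
manual_event_table <- function(values_list, transformed = FALSE) {
  nm <- names(values_list)
  roles <- sub("[0-9]*$", "", nm)
  role_map <- c(M = "marker", BC = "barcode", Bead = "bead", DNA = "dna",
                EL = "event_length", Time = "time")
  ch <- data.frame(name = nm, metal = nm, marker = nm,
                   role = unname(role_map[sub("^([A-Za-z]+).*$", "\\1", nm)]),
                   lineage = FALSE, embedding = FALSE,
                   stringsAsFactors = FALSE)
  event_table(do.call(cbind, values_list), ch, transformed = transformed)
}

# Binomial cluster counts with a per-sample logit-normal random effect:
# the generative model the GLMM assumes.
simulate_glmm_counts <- function(base, beta, sigma, n_per_samp, seed,
                                 groups = rep(c("CON", "MS"), each = 11)) {
  set.seed(seed)
  K <- length(base); S <- length(groups)
  g <- as.integer(factor(groups)) - 1L
  counts <- matrix(0L, K, S,
                   dimnames = list(paste0("c", seq_len(K)),
                                   paste0("s", seq_len(S))))
  for (k in seq_len(K)) for (s in seq_len(S)) {
    eta <- qlogis(base[k]) + beta[k] * g[s] + rnorm(1, 0, sigma)
    counts[k, s] <- rbinom(1, n_per_samp, plogis(eta))
  }
  cluster_counts(counts, setNames(rep(n_per_samp, S), colnames(counts)),
                 groups)
}

# Synthetic 2-D "embedding": two background blobs plus a spiked region whose
# weight doubles in the second group.  Returns coords, sample ids, component
# labels and metadata.
simulate_spiked_embedding <- function(n_per_sample = 2000, w_base = 0.05,
                                      w_spiked = 0.10, seed = 9) {
  set.seed(seed)
  md <- data.frame(sample_id = paste0("S", 1:22),
                   group = rep(c("A", "B"), each = 11))
  coords <- matrix(numeric(0), 0, 2)
  samp <- character(0); comp <- character(0)
  centers <- rbind(bg1 = c(-3, 0), bg2 = c(0, 3), spike = c(6, 0))
  for (s in seq_len(nrow(md))) {
    w <- if (md$group[s] == "B") w_spiked else w_base
    k <- sample(rownames(centers), n_per_sample, TRUE,
                prob = c((1 - w) / 2, (1 - w) / 2, w))
    coords <- rbind(coords,
                    centers[k, ] + matrix(rnorm(n_per_sample * 2), ncol = 2))
    samp <- c(samp, rep(md$sample_id[s], n_per_sample))
    comp <- c(comp, k)
  }
  list(coords = coords, sample_id = samp, component = comp, metadata = md)
}

# Gaussian blob data for clustering/embedding recovery tests.
make_blobs <- function(n, centers, sigma, seed) {
  set.seed(seed)
  k <- nrow(centers)
  lab <- sample(seq_len(k), n, replace = TRUE)
  X <- centers[lab, , drop = FALSE] +
    matrix(rnorm(n * ncol(centers), 0, sigma), n)
  list(X = X, labels = lab)
}
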