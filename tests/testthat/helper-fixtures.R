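# Fixtures are built in code at test time; nothing is stored on disk.

# tiny hand-made dataset: one condition column, descriptor values chosen so
# Box-Jenkins statistics are easy to verify by hand
tiny_train <- function() {
  mtqsar_dataset(
    ids = paste0("t", 1:5),
    response = c(1, 1, -1, -1, 1),
    conditions = data.frame(bt = c("e", "e", "e", "f", "f")),
    descriptors = cbind(D1 = c(1, 5, 0, 10, 3),
                        D2 = c(2, 2, 2, 2, 2))   # constant on purpose
  )
}

# synthetic dataset + three-set split + deviation features, the standard
# modelling pipeline front end used across tests
make_pipeline <- function(n_rows = 250, n_descriptors = 6,
                          cards = c(3, 2), seed = 11, effect_size = 1,
                          method = 1, val_fraction = 0.22,
                          test_fraction = 0.2, active_fraction = 0.74) {
  ds <- generate_synthetic(synthetic_spec(
    n_rows = n_rows, n_descriptors = n_descriptors,
    condition_cardinalities = cards, active_fraction = active_fraction,
    effect_size = effect_size, noise_sd = 0.5, seed = seed))
  sp <- split_random(ds, val_fraction, seed = seed)
  sp <- split_subtrain_test(sp, test_fraction, seed = seed)
  training <- subset_rows(ds, sp$id[sp$set != "validation"])
  bj <- fit_boxjenkins(training, method = method)
  feats <- predict(bj, ds)
  sub_idx <- match(sp$id[sp$set == "sub-training"], ds$ids)
  list(ds = ds, sp = sp, training = training, bj = bj, feats = feats,
       sub_idx = sub_idx, Xsub = feats[sub_idx, , drop = FALSE],
       ysub = ds$response[sub_idx],
       sets = sp$set[match(ds$ids, sp$id)])
}

# brute-force Mann-Whitney pair-counting AUROC (independent oracle)
pair_count_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# two well-separated descriptor blobs (for kMCA and kNN fixtures)
two_blob_dataset <- function(n = 120, seed = 3, gap = 12) {
  set.seed(seed)
  blob <- rep(1:2, each = n / 2)
  X <- cbind(X1 = rnorm(n, mean = ifelse(blob == 1, 0, gap), sd = 1),
             X2 = rnorm(n, mean = ifelse(blob == 1, 0, gap), sd = 1))
  y <- ifelse(blob == 1, 1L, -1L)
  ds <- mtqsar_dataset(ids = paste0("b", seq_len(n)), response = y,
                       conditions = data.frame(ct = rep("all", n)),
                       descriptors = X)
  attr(ds, "blob") <- blob
  ds
}
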