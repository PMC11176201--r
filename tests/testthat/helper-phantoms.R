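# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; cohorts are cached per session so several tests can
# reuse one extraction.

# --- geometric phantoms ----------------------------------------------------

# hollow sphere shell: outer radius R, inner radius r (mm), given spacing
sphere_shell <- function(R = 20, r = 16, spacing = c(1, 1, 1),
                         pad = 4L, value_bg = 0) {
  n <- ceiling(2 * R / spacing) + 2L * pad
  ctr <- (n - 1) * spacing / 2
  ax <- lapply(1:3, function(k) ((seq_len(n[k]) - 1) * spacing[k] - ctr[k])^2)
  q <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  img <- volume_image(array(value_bg, n), spacing)
  mask <- wall_mask(array(as.integer(q <= R^2 & q > r^2), n), img)
  list(image = img, mask = mask)
}

# small hollow box shell (fast, exactly known geometry)
box_shell <- function(lo = 3L, hi = 9L, n = 12L) {
  m <- array(0L, c(n, n, n))
  m[lo:hi, lo:hi, lo:hi] <- 1L
  m[(lo + 1):(hi - 1), (lo + 1):(hi - 1), (lo + 1):(hi - 1)] <- 0L
  img <- volume_image(array(0, c(n, n, n)), c(1, 1, 1))
  list(image = img, mask = wall_mask(m, img))
}

# --- brute-force co-occurrence oracles -------------------------------------

# enumerate co-occurring level pairs one by one; the reference for glcm()
glcm_oracle <- function(levels, mask, off, nbins, symmetric = TRUE,
                        normalize = TRUE) {
  d <- dim(levels)
  nd <- length(d)
  cnt <- matrix(0, nbins, nbins)
  it <- as.matrix(expand.grid(lapply(d, seq_len)))
  for (rr in seq_len(nrow(it))) {
    a <- it[rr, ]
    b <- a + off
    if (any(b < 1) || any(b > d)) next
    ai <- matrix(a, 1); bi <- matrix(b, 1)
    if (mask[ai] == 0 || mask[bi] == 0) next
    li <- levels[ai]; lj <- levels[bi]
    if (li < 0 || lj < 0 || li >= nbins || lj >= nbins) next
    cnt[li + 1, lj + 1] <- cnt[li + 1, lj + 1] + 1
  }
  if (symmetric) cnt <- cnt + t(cnt)
  if (normalize && sum(cnt) > 0) cnt <- cnt / sum(cnt)
  cnt
}

# Haralick statistics computed directly from the enumerated pair list,
# without forming a matrix first — an independent route to the same values
haralick_pair_oracle <- function(levels, mask, off, nbins) {
  d <- dim(levels)
  it <- as.matrix(expand.grid(lapply(d, seq_len)))
  li <- integer(0); lj <- integer(0)
  for (rr in seq_len(nrow(it))) {
    a <- it[rr, ]; b <- a + off
    if (any(b < 1) || any(b > d)) next
    ai <- matrix(a, 1); bi <- matrix(b, 1)
    if (mask[ai] == 0 || mask[bi] == 0) next
    la <- levels[ai]; lb <- levels[bi]
    if (la < 0 || lb < 0 || la >= nbins || lb >= nbins) next
    li <- c(li, la, lb); lj <- c(lj, lb, la)  # symmetric: both orders
  }
  if (!length(li)) return(NULL)
  w <- rep(1 / length(li), length(li))
  mx <- sum(w * li); my <- sum(w * lj)
  sx <- sqrt(sum(w * (li - mx)^2)); sy <- sqrt(sum(w * (lj - my)^2))
  pr <- table(paste(li, lj)) / length(li)
  c(contrast = sum(w * (li - lj)^2),
    dissimilarity = sum(w * abs(li - lj)),
    homogeneity = sum(w / (1 + (li - lj)^2)),
    energy = sum(pr^2),
    entropy = -sum(pr * log2(pr)),
    correlation = if (sx == 0 || sy == 0) 0 else
      sum(w * (li - mx) * (lj - my)) / (sx * sy),
    variance = sum(w * (li - mx)^2),
    sum_average = sum(w * (li + lj)),
    cluster_shade = sum(w * (li + lj - mx - my)^3),
    cluster_prominence = sum(w * (li + lj - mx - my)^4))
}

# pair-counting AUC (Mann-Whitney with half credit for ties)
auc_pair_oracle <- function(truth, scores) {
  p <- scores[truth == "positive"]; n <- scores[truth == "negative"]
  tot <- 0
  for (a in p) for (b in n)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p) * length(n))
}

# --- cached synthetic cohorts ---------------------------------------------

.cohort_cache <- new.env(parent = emptyenv())

# texture sweep kept lean so cohort extraction stays fast in tests
lean_texture_config <- function() {
  texture_config(distances = c(1, 2), bins = c(8, 16), windows = c(5, 9))
}

# clinical model with no class difference (for cohorts where only texture
# may differ)
flat_clinical <- function() {
  list(age = list(mean = c(64, 64), sd = c(8, 8)),
       bmi = list(mean = c(27, 27), sd = c(4, 4)),
       prostate_size = list(mean = c(45, 45), sd = c(13, 13)))
}

# generate (or fetch) a cohort and its extracted feature table
test_cohort <- function(seed, texture_effect, n_negative = 23L,
                        n_positive = 17L, clinical_model = flat_clinical(),
                        txc = lean_texture_config(), label = "") {
  key <- paste(label, seed, texture_effect, n_negative, n_positive,
               length(txc$bins) * length(txc$windows) * length(txc$distances),
               sep = "_")
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cfg <- synthetic_config(n_negative = n_negative, n_positive = n_positive,
                          texture_effect = texture_effect,
                          clinical_model = clinical_model, seed = seed)
  d <- tempfile("cohort")
  generate_cohort(cfg, d)
  man <- load_manifest(file.path(d, "manifest.csv"), quiet = TRUE)
  tab <- extract_features(man, txc, quiet = TRUE)
  unlink(d, recursive = TRUE)
  out <- list(table = tab, labels = man$label, manifest = man)
  .cohort_cache[[key]] <- out
  out
}
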