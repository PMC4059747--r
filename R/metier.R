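#' Bray-Curtis dissimilarity between two catch profiles
#'
#' `BCD = 1 - 2 * C / (S_i + S_j)` where `C` is the summed species-wise
#' minimum of the two profiles (the shared catch) and `S_i`, `S_j` the profile
#' totals. Symmetric, bounded in `[0, 1]`, zero iff the profiles are equal,
#' and invariant to rescaling both profiles by a common factor.
#'
#' @param x,y Nonnegative numeric vectors over the same species universe.
#' @return Dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(A = 6, B = 2), c(A = 2, B = 6))  # 0.5
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  si <- sum(x); sj <- sum(y)
  if (si + sj == 0) stop("Bray-Curtis undefined for two all-zero profiles")
  max(1 - 2 * sum(pmin(x, y)) / (si + sj), 0)
}

#' Cross-dissimilarity matrix between profile sets
#'
#' @param x Numeric matrix, rows are profiles.
#' @param y Numeric matrix with the same columns (defaults to `x`).
#' @param method `"bray_curtis"`, `"euclidean"` or `"manhattan"`.
#' @return `nrow(x)` x `nrow(y)` dissimilarity matrix.
#' @export
cross_dissim <- function(x, y = x,
                         method = c("bray_curtis", "euclidean", "manhattan")) {
  method <- match.arg(method)
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y))
  if (method == "bray_curtis") {
    cmat <- matrix(0, nrow(x), nrow(y))
    for (s in seq_len(ncol(x)))
      cmat <- cmat + outer(x[, s], y[, s], pmin)
    tot <- outer(rowSums(x), rowSums(y), `+`)
    if (any(tot == 0)) stop("Bray-Curtis undefined for all-zero profiles")
    pmax(1 - 2 * cmat / tot, 0)  # clamp away negative rounding residue
  } else if (method == "euclidean") {
    d2 <- outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * tcrossprod(x, y)
    sqrt(pmax(d2, 0))
  } else {
    d <- matrix(0, nrow(x), nrow(y))
    for (s in seq_len(ncol(x)))
      d <- d + abs(outer(x[, s], y[, s], `-`))
    d
  }
}

#' Partitioning Around Medoids (BUILD + SWAP)
#'
#' k-medoids clustering to a local optimum of the total cost
#' `sum_i d(i, nearest medoid)`. BUILD seeds greedily (first medoid minimises
#' the summed dissimilarity, each further medoid maximises the cost
#' reduction); SWAP repeatedly applies the single medoid/non-medoid exchange
#' with the largest cost decrease until none improves. Ties are broken by
#' lowest index throughout, so the result is deterministic.
#'
#' @param x Profile matrix (rows = observations), or `NULL` when `dmat` is
#'   given.
#' @param k Number of medoids, `1 <= k < n`.
#' @param method Dissimilarity, see [cross_dissim()].
#' @param dmat Optional precomputed dissimilarity matrix.
#' @return List with `medoids` (sorted indices), `assignment` (index into
#'   `medoids` per observation) and `cost` (total dissimilarity).
#' @export
pam_medoids <- function(x, k, method = "bray_curtis", dmat = NULL) {
  if (is.null(dmat)) dmat <- cross_dissim(x, x, method)
  n <- nrow(dmat)
  if (k >= n) stop("k must be smaller than the number of observations")
  if (k < 1) stop("k must be at least 1")
  # BUILD
  med <- which.min(colSums(dmat))
  dn <- dmat[, med]
  while (length(med) < k) {
    gain <- colSums(pmax(dn - dmat, 0))
    gain[med] <- -Inf
    med <- c(med, which.max(gain))
    dn <- pmin(dn, dmat[, med[length(med)]])
  }
  med <- sort(med)
  # SWAP (steepest descent); k = 1 needs none, BUILD is already optimal there
  while (k > 1) {
    dmed <- dmat[, med, drop = FALSE]
    nearest <- max.col(-dmed, ties.method = "first")
    dn <- dmed[cbind(seq_len(n), nearest)]
    dmed2 <- dmed
    dmed2[cbind(seq_len(n), nearest)] <- Inf
    ds <- dmed2[cbind(seq_len(n), max.col(-dmed2, ties.method = "first"))]
    memb <- matrix(0, n, k)
    memb[cbind(seq_len(n), nearest)] <- 1
    best <- list(delta = -1e-12, pos = NA_integer_, h = NA_integer_)
    for (h in setdiff(seq_len(n), med)) {
      a <- dmat[, h]
      base <- pmin(a - dn, 0)               # points keeping their medoid
      alt <- pmin(a, ds) - dn               # points losing medoid at position m
      base_by_m <- as.vector(crossprod(memb, base))
      alt_by_m <- as.vector(crossprod(memb, alt))
      deltas <- sum(base) - base_by_m + alt_by_m
      j <- which.min(deltas)
      if (deltas[j] < best$delta)
        best <- list(delta = deltas[j], pos = j, h = h)
    }
    if (is.na(best$pos)) break
    med <- sort(c(med[-best$pos], best$h))
  }
  dmed <- dmat[, med, drop = FALSE]
  assignment <- max.col(-dmed, ties.method = "first")
  cost <- sum(dmed[cbind(seq_len(n), assignment)])
  list(medoids = med, assignment = assignment, cost = cost)
}

#' CLARA: PAM on random subsamples, scored on the full data
#'
#' Draws `n_samples` random subsamples of `sample_size` observations, runs
#' [pam_medoids()] on each, assigns the whole dataset to the sample's
#' medoids, and keeps the medoid set with the lowest full-data average
#' dissimilarity. After the first sample, the current best medoids are always
#' included in the next subsample (classic CLARA refinement). Deterministic
#' for a fixed seed. When `sample_size >= n` a single PAM on the full data is
#' run instead.
#'
#' @param x Profile matrix.
#' @param k Number of clusters.
#' @param n_samples Number of random subsamples (default 100).
#' @param sample_size Size of each subsample (default 1000).
#' @param method Dissimilarity, see [cross_dissim()].
#' @param seed Optional integer seed.
#' @return List with `medoids` (row indices into `x`), `assignment`,
#'   `avg_dissim` (full-data average dissimilarity) and `cost`.
#' @export
clara_medoids <- function(x, k, n_samples = 100, sample_size = 1000,
                          method = "bray_curtis", seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(sample_size >= k)
  if (!is.null(seed)) set.seed(seed)
  if (sample_size >= n) {
    fit <- pam_medoids(x, k, method)
    return(list(medoids = fit$medoids, assignment = fit$assignment,
                avg_dissim = fit$cost / n, cost = fit$cost))
  }
  best <- NULL
  for (s in seq_len(n_samples)) {
    base <- if (is.null(best)) integer(0) else best$medoids
    pool <- setdiff(seq_len(n), base)
    idx <- sort(c(base, sample(pool, sample_size - length(base))))
    fit <- pam_medoids(x[idx, , drop = FALSE], k, method)
    med <- idx[fit$medoids]
    dmed <- cross_dissim(x, x[med, , drop = FALSE], method)
    assignment <- max.col(-dmed, ties.method = "first")
    avg <- mean(dmed[cbind(seq_len(n), assignment)])
    if (is.null(best) || avg < best$avg_dissim)
      best <- list(medoids = med, assignment = assignment,
                   avg_dissim = avg, cost = avg * n)
  }
  best
}

#' Average silhouette width
#'
#' For each observation `i`, `a_i` is its mean dissimilarity to its own
#' cluster (excluding itself) and `b_i` the minimum over other clusters of
#' the mean dissimilarity to that cluster; the silhouette is
#' `s_i = (b_i - a_i) / max(a_i, b_i)`. Observations in singleton clusters,
#' and degenerate cases with `a_i = b_i = 0`, score 0 by convention. The
#' dissimilarities are computed blockwise so no full `n x n` matrix is held.
#'
#' @param x Profile matrix.
#' @param assignment Integer cluster labels (>= 2 nonempty clusters).
#' @param method Dissimilarity, see [cross_dissim()].
#' @param block Block size for the row-wise sweep.
#' @return Mean silhouette over all observations, in `[-1, 1]`.
#' @export
asw <- function(x, assignment, method = "bray_curtis", block = 500L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(assignment) == n)
  labs <- sort(unique(assignment))
  if (length(labs) < 2L) stop("silhouette needs at least 2 clusters")
  gi <- match(assignment, labs)
  sizes <- tabulate(gi, nbins = length(labs))
  memb <- matrix(0, n, length(labs))
  memb[cbind(seq_len(n), gi)] <- 1
  s <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    db <- cross_dissim(x[rows, , drop = FALSE], x, method)
    sums <- db %*% memb                      # |rows| x k summed dissimilarity
    own <- gi[rows]
    a <- (sums[cbind(seq_along(rows), own)]) / pmax(sizes[own] - 1L, 1L)
    means <- sweep(sums, 2, sizes, "/")
    means[cbind(seq_along(rows), own)] <- Inf
    b <- apply(means, 1, min)
    denom <- pmax(a, b)
    si <- ifelse(denom == 0, 0, (b - a) / denom)
    si[sizes[own] == 1L] <- 0
    s[rows] <- si
  }
  mean(s)
}

#' Metier model constructor
#'
#' A fitted metier classifier: `k` medoid catch profiles (actual training
#' records), the dissimilarity they were fitted under, and the fuzziness
#' exponent used by [classify_metier()].
#'
#' @param medoids Numeric matrix, one row per medoid, columns = species codes.
#' @param labels Unique labels, one per medoid (e.g. DCF metier codes).
#' @param method Dissimilarity name.
#' @param m Fuzziness exponent, `> 1` (default 2).
#' @return Object of class `metier_model`.
#' @export
metier_model <- function(medoids, labels = NULL,
                         method = "bray_curtis", m = 2) {
  medoids <- as.matrix(medoids)
  if (is.null(labels)) labels <- paste0("MET_", seq_len(nrow(medoids)))
  stopifnot(length(labels) == nrow(medoids), !anyDuplicated(labels), m > 1)
  rownames(medoids) <- labels
  structure(list(k = nrow(medoids), medoids = medoids,
                 species = colnames(medoids), labels = labels,
                 method = method, m = m),
            class = "metier_model")
}

#' @export
print.metier_model <- function(x, ...) {
  cat("metier model:", x$k, "medoids over", length(x$species),
      "species,", x$method, "dissimilarity, fuzziness m =", x$m, "\n")
  invisible(x)
}

#' Discover metiers in a logbook database
#'
#' Runs [clara_medoids()] for each candidate number of clusters and picks the
#' `k` maximising the full-data average silhouette width. Options mirror the
#' usual pre-treatments: standardisation by trip length in days (catch per
#' day at sea) and outlier removal (records whose nearest-neighbour
#' dissimilarity exceeds the 99th percentile of all pairwise dissimilarities
#' are dropped).
#'
#' @param lb Logbook data frame (see [read_logbook()]), or a plain profile
#'   matrix.
#' @param k_range Candidate cluster counts (e.g. `2:30`).
#' @param method Dissimilarity, see [cross_dissim()].
#' @param n_samples,sample_size CLARA parameters (defaults 100 and 1000).
#' @param standardize_days Divide each profile by its trip length in days.
#' @param remove_outliers Drop outlying records before clustering.
#' @param m Fuzziness exponent stored in the returned model.
#' @param seed Optional integer seed (CLARA subsampling).
#' @return A [metier_model()] for the best `k`, with attributes
#'   `silhouette_profile` (data frame of k, asw), `assignment` (hard cluster
#'   per used record) and `used` (row indices that entered the clustering).
#' @export
discover_metiers <- function(lb, k_range = 2:30, method = "bray_curtis",
                             n_samples = 100, sample_size = 1000,
                             standardize_days = FALSE, remove_outliers = FALSE,
                             m = 2, seed = NULL) {
  if (length(k_range) == 0L) stop("empty k_range")
  x <- if (is.matrix(lb)) lb else catch_matrix(lb)
  if (standardize_days) {
    if (is.matrix(lb)) stop("standardize_days needs a logbook data frame")
    days <- as.numeric(difftime(lb$arrival, lb$departure, units = "days"))
    x <- x / pmax(days, 1 / 24)
  }
  used <- seq_len(nrow(x))
  if (remove_outliers && nrow(x) > 2L) {
    d <- cross_dissim(x, x, method)
    diag(d) <- Inf
    nnd <- apply(d, 1, min)
    cutoff <- stats::quantile(d[is.finite(d)], 0.99)
    keep <- nnd <= cutoff
    used <- used[keep]
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("need at least 2 records")
  fits <- list()
  profile <- data.frame(k = integer(), asw = numeric())
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- clara_medoids(x, k, n_samples, sample_size, method,
                         seed = if (is.null(seed)) NULL else seed + i)
    a <- if (length(unique(fit$assignment)) < 2L) 0
         else asw(x, fit$assignment, method)
    fits[[i]] <- fit
    profile <- rbind(profile, data.frame(k = k, asw = a))
  }
  best <- which.max(profile$asw)
  fit <- fits[[best]]
  model <- metier_model(x[fit$medoids, , drop = FALSE],
                        method = method, m = m)
  attr(model, "silhouette_profile") <- profile
  attr(model, "assignment") <- fit$assignment
  attr(model, "used") <- used
  model
}

#' Fuzzy classification of catch profiles against a metier model
#'
#' Memberships follow the fuzzy-clustering rule
#' `u_c = d_c^(-2/(m-1)) / sum_c' d_c'^(-2/(m-1))` where `d_c` is the
#' dissimilarity to medoid `c`; they sum to 1. A record at zero distance from
#' a medoid gets full membership there. As `m -> 1+` the memberships approach
#' the crisp nearest-medoid indicator. Species present in the records but not
#' in the model (or vice versa) are aligned by adding zero columns. Hard
#' labels take the highest membership, ties to the lower medoid index.
#'
#' @param lb Logbook data frame or profile matrix.
#' @param model A [metier_model()].
#' @return Data frame with `label` (hard metier), `confidence` (top
#'   membership) and one `u_<label>` column per medoid. All-zero records are
#'   unclassifiable: `NA` label, memberships `NA`.
#' @export
classify_metier <- function(lb, model) {
  stopifnot(inherits(model, "metier_model"))
  x <- if (is.matrix(lb)) lb else catch_matrix(lb)
  if (is.null(colnames(x))) stop("profiles must have species column names")
  all_sp <- union(colnames(x), model$species)
  pad <- function(mat) {
    out <- matrix(0, nrow(mat), length(all_sp), dimnames = list(NULL, all_sp))
    out[, colnames(mat)] <- mat
    out
  }
  xp <- pad(x)
  mp <- pad(model$medoids)
  ok <- rowSums(xp) > 0
  u <- matrix(NA_real_, nrow(xp), model$k)
  if (any(ok)) {
    d <- cross_dissim(xp[ok, , drop = FALSE], mp, model$method)
    expo <- 2 / (model$m - 1)
    uu <- t(vapply(seq_len(nrow(d)), function(i) {
      di <- d[i, ]
      if (any(di == 0)) {
        z <- as.numeric(di == 0)
        z / sum(z)
      } else {
        # log-scale for numerical stability at small m
        lw <- -expo * log(di)
        w <- exp(lw - max(lw))
        w / sum(w)
      }
    }, numeric(model$k)))
    u[ok, ] <- uu
  }
  colnames(u) <- paste0("u_", model$labels)
  hard <- rep(NA_character_, nrow(xp))
  conf <- rep(NA_real_, nrow(xp))
  if (any(ok)) {
    idx <- max.col(u[ok, , drop = FALSE], ties.method = "first")
    hard[ok] <- model$labels[idx]
    conf[ok] <- u[ok, , drop = FALSE][cbind(seq_len(sum(ok)), idx)]
  }
  out <- data.frame(label = hard, confidence = conf, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(u))
}

#' Assign DCF labels to discovered medoids from reference profiles
#'
#' Formalises the metier-editing step: each medoid takes the label of the
#' nearest reference catch profile (greedy one-to-one assignment, closest
#' pairs first). With more medoids than references the leftovers keep their
#' generic labels.
#'
#' @param model A [metier_model()].
#' @param reference Labelled profile matrix (rownames = labels), e.g.
#'   [reference_profiles()].
#' @return The model with labels replaced.
#' @export
label_metiers <- function(model, reference) {
  stopifnot(inherits(model, "metier_model"), !is.null(rownames(reference)))
  all_sp <- union(model$species, colnames(reference))
  pad <- function(mat) {
    out <- matrix(0, nrow(mat), length(all_sp), dimnames = list(rownames(mat), all_sp))
    out[, colnames(mat)] <- mat
    out
  }
  d <- cross_dissim(pad(model$medoids), pad(reference), model$method)
  labels <- model$labels
  for (step in seq_len(min(nrow(d), ncol(d)))) {
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    labels[ij[1]] <- rownames(reference)[ij[2]]
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
  }
  metier_model(model$medoids, labels = labels, method = model$method, m = model$m)
}

#' Save / load a metier model as delimited text
#'
#' One row per medoid: a `label` column followed by one column per species
#' code; the dissimilarity and fuzziness are kept in header comment lines.
#'
#' @param model A [metier_model()].
#' @param path File path.
#' @return `read_metier_model` returns a `metier_model`.
#' @export
write_metier_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# method=", model$method), paste0("# m=", model$m)), con)
  d <- data.frame(label = model$labels, model$medoids, check.names = FALSE)
  utils::write.table(d, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metier_model
#' @export
read_metier_model <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  method <- sub("^# method=", "", grep("^# method=", hdr, value = TRUE))
  m <- as.numeric(sub("^# m=", "", grep("^# m=", hdr, value = TRUE)))
  d <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                         sep = ",", check.names = FALSE,
                         stringsAsFactors = FALSE)
  med <- as.matrix(d[, setdiff(names(d), "label"), drop = FALSE])
  metier_model(med, labels = d$label, method = method, m = m)
}
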