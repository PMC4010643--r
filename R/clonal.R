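#' Select variants for clonal analysis
#'
#' The clonal reconstruction input set: the candidate driver mutations
#' plus `n_random` somatic mutations sampled uniformly without replacement
#' from the rest of the genome (deterministic given the seed).
#'
#' @param candidates data.frame of candidate (driver) variants.
#' @param all_snvs data.frame of all depth-filtered somatic SNVs.
#' @param n_random number of random additions (default 50).
#' @param seed RNG seed.
#' @return row-bound data.frame of candidates plus the random draw, with a
#'   `selection` column ("candidate"/"random").
#' @export
select_variants <- function(candidates, all_snvs, n_random = 50, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  pool <- all_snvs[!(key(all_snvs) %in% key(candidates)), , drop = FALSE]
  n <- min(n_random, nrow(pool))
  draw <- pool[sort(sample.int(nrow(pool), n)), , drop = FALSE]
  out <- rbind(
    if (nrow(candidates)) cbind(candidates, selection = "candidate"),
    if (nrow(draw)) cbind(draw, selection = "random"))
  rownames(out) <- NULL
  out
}

#' Estimate per-variant cellular prevalence
#'
#' Converts the variant allele fraction into the fraction of tumour cells
#' carrying the mutation, adjusting for local total copy number, mutation
#' multiplicity and sample purity:
#' \deqn{f = VAF \cdot (t c + 2 (1 - t)) / (t m)}
#' with VAF = alt_reads / depth, purity `t`, locus total copy number `c`
#' and multiplicity `m` (copies carrying the mutation, default 1).
#' Estimates are clamped to [0, 1] with the clamping recorded; variants at
#' copy-number-zero loci are excluded (with a message).
#'
#' @param obs data.frame with `alt_reads`, `depth`, `total_cn`, `purity`,
#'   and optionally `multiplicity`.
#' @return the data.frame with `vaf`, `prevalence` and `clamped` columns
#'   appended; CN-zero rows dropped.
#' @export
estimate_prevalence <- function(obs) {
  stopifnot(all(obs$depth > 0), all(obs$purity > 0 & obs$purity <= 1))
  if (is.null(obs$multiplicity)) obs$multiplicity <- 1
  drop <- obs$total_cn == 0
  if (any(drop)) {
    message(sum(drop), " variants at copy-number-zero loci excluded")
    obs <- obs[!drop, , drop = FALSE]
  }
  obs$vaf <- obs$alt_reads / obs$depth
  raw <- obs$vaf * (obs$purity * obs$total_cn + 2 * (1 - obs$purity)) /
    (obs$purity * obs$multiplicity)
  obs$prevalence <- pmin(pmax(raw, 0), 1)
  obs$clamped <- raw > 1 | raw < 0
  obs
}

# log(sum(exp(x))) without overflow
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Cluster cellular prevalences into clones
#'
#' Fits a Dirichlet-process binomial mixture over cellular prevalence:
#' each cluster has a prevalence \eqn{\phi \in [0,1]} (uniform base
#' measure, discretized on a grid), and a variant in that cluster
#' contributes alt reads Binomial(depth, \eqn{\phi s_i}) where
#' \eqn{s_i = t m_i / (t c_i + 2(1 - t))} is the variant's
#' prevalence-to-VAF scale. Inference is collapsed Gibbs sampling with
#' grid-integrated new-cluster weights, per-cluster grid resampling of
#' \eqn{\phi}, and concentration resampling under a Gamma(1,1) prior.
#' The reported partition is the posterior sample closest (by Dahl's
#' least-squares criterion) to the posterior similarity matrix. A
#' deterministic fallback (`method = "bins"`) bins prevalence estimates at
#' width 0.1 and merges adjacent occupied bins.
#'
#' @param obs data.frame as returned by [estimate_prevalence()].
#' @param prior_concentration initial DP concentration.
#' @param n_iterations total Gibbs sweeps (default 5000).
#' @param burn_in discarded sweeps (default 1000).
#' @param seed RNG seed (mandatory for `method = "dp"`).
#' @param grid_size number of prevalence grid points on [0, 1].
#' @param thin keep every `thin`-th post-burn-in partition.
#' @param method `"dp"` (sampler) or `"bins"` (deterministic fallback).
#' @return object of class `clone_fit`.
#' @export
cluster_prevalences <- function(obs, prior_concentration = 1,
                                n_iterations = 5000, burn_in = 1000,
                                seed, grid_size = 201, thin = 5,
                                method = c("dp", "bins")) {
  method <- match.arg(method)
  stopifnot(nrow(obs) >= 1)
  if (is.null(obs$prevalence)) obs <- estimate_prevalence(obs)
  if (method == "bins") return(.cluster_bins(obs))
  if (missing(seed)) stop("a seed is mandatory for the DP sampler")
  set.seed(seed)

  n <- nrow(obs)
  a <- obs$alt_reads; d <- obs$depth
  t <- obs$purity; m <- obs$multiplicity %||% rep(1, n)
  s <- t * m / (t * obs$total_cn + 2 * (1 - t))
  grid <- seq(0, 1, length.out = grid_size)
  # per-observation log-likelihood over the prevalence grid (fixed)
  p_mat <- pmin(outer(s, grid), 1)
  logL <- matrix(stats::dbinom(rep(a, grid_size), rep(d, grid_size),
                               as.vector(p_mat), log = TRUE),
                 nrow = n)
  int_new <- apply(logL, 1, .logsumexp) - log(grid_size)  # base-measure integral

  draw_phi <- function(members) {
    lp <- if (length(members) == 1) logL[members, ] else
      colSums(logL[members, , drop = FALSE])
    w <- exp(lp - max(lp))
    sample.int(grid_size, 1, prob = w)
  }

  z <- rep(1L, n)
  phi_idx <- draw_phi(seq_len(n))
  alpha <- prior_concentration
  k_trace <- integer(n_iterations)
  kept <- list()

  for (it in seq_len(n_iterations)) {
    for (i in seq_len(n)) {
      zi <- z[i]
      z[i] <- NA_integer_
      counts <- tabulate(z[!is.na(z)], nbins = max(zi, max(z, na.rm = TRUE)))
      live <- which(counts > 0)
      logw <- log(counts[live]) + logL[cbind(i, phi_idx[live])]
      logw <- c(logw, log(alpha) + int_new[i])
      w <- exp(logw - max(logw))
      pick <- sample.int(length(w), 1, prob = w)
      if (pick <= length(live)) {
        z[i] <- live[pick]
      } else {
        free <- which(counts == 0)
        newk <- if (length(free)) free[1] else length(counts) + 1L
        z[i] <- newk
        phi_idx[newk] <- draw_phi(i)
      }
    }
    # relabel to contiguous cluster ids
    labels <- sort(unique(z))
    z <- match(z, labels)
    phi_idx <- phi_idx[labels]
    k <- length(labels)
    # resample cluster prevalences
    for (kk in seq_len(k)) phi_idx[kk] <- draw_phi(which(z == kk))
    # resample concentration (Escobar & West) under Gamma(1,1)
    eta <- stats::rbeta(1, alpha + 1, n)
    odds <- (1 + k - 1) / (n * (1 - log(eta)))
    comp <- stats::runif(1) < odds / (1 + odds)
    alpha <- stats::rgamma(1, 1 + k - ifelse(comp, 0, 1),
                           1 - log(eta))
    k_trace[it] <- k
    if (it > burn_in && (it - burn_in) %% thin == 0)
      kept[[length(kept) + 1]] <- list(z = z, phi = grid[phi_idx])
  }

  # posterior similarity matrix and Dahl's least-squares partition
  S <- length(kept)
  psm <- matrix(0, n, n)
  for (kp in kept) {
    eq <- outer(kp$z, kp$z, "==")
    psm <- psm + eq
  }
  psm <- psm / S
  best <- which.min(vapply(kept, function(kp)
    sum((outer(kp$z, kp$z, "==") - psm)^2), numeric(1)))
  z_hat <- kept[[best]]$z

  clusters <- do.call(rbind, lapply(sort(unique(z_hat)), function(kk) {
    members <- which(z_hat == kk)
    lp <- if (length(members) == 1) logL[members, ] else
      colSums(logL[members, , drop = FALSE])
    w <- exp(lp - max(lp)); w <- w / sum(w)
    data.frame(cluster = kk, prevalence = sum(w * grid),
               n_variants = length(members))
  }))
  structure(list(clusters = clusters, assignments = z_hat,
                 n_clusters = nrow(clusters), psm = psm,
                 k_trace = k_trace, obs = obs, method = "dp",
                 settings = list(n_iterations = n_iterations,
                                 burn_in = burn_in, thin = thin,
                                 grid_size = grid_size, seed = seed)),
            class = "clone_fit")
}

# deterministic fallback: 0.1-width bins, adjacent occupied bins merged
.cluster_bins <- function(obs, width = 0.1) {
  bin <- pmin(floor(obs$prevalence / width), 1 / width - 1) + 1
  occupied <- sort(unique(bin))
  merged <- cumsum(c(1, diff(occupied) > 1))
  cluster_of_bin <- stats::setNames(merged, occupied)
  z <- unname(cluster_of_bin[as.character(bin)])
  clusters <- do.call(rbind, lapply(sort(unique(z)), function(kk)
    data.frame(cluster = kk,
               prevalence = mean(obs$prevalence[z == kk]),
               n_variants = sum(z == kk))))
  structure(list(clusters = clusters, assignments = z,
                 n_clusters = nrow(clusters), psm = NULL,
                 k_trace = integer(0), obs = obs, method = "bins",
                 settings = list(width = width)),
            class = "clone_fit")
}

#' @export
print.clone_fit <- function(x, ...) {
  cat("<clone_fit> ", x$n_clusters, " clonal cluster(s) over ",
      nrow(x$obs), " variants [", x$method, "]\n", sep = "")
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' @export
summary.clone_fit <- function(object, ...) {
  cat("Clonal clustering (", object$method, ")\n", sep = "")
  print(object$clusters, row.names = FALSE)
  if (length(object$k_trace)) {
    cat("\nCluster-count trace (post-burn-in):\n")
    bi <- object$settings$burn_in
    print(table(object$k_trace[(bi + 1):length(object$k_trace)]))
  }
  invisible(object)
}

#' @export
plot.clone_fit <- function(x, ...) {
  graphics::hist(x$obs$prevalence, breaks = seq(0, 1, 0.05),
                 xlab = "cellular prevalence", main = "Clonal clusters",
                 col = "grey85", border = "white", ...)
  graphics::abline(v = x$clusters$prevalence, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Clustering sensitivity to the assumed DNA index
#'
#' Copy-number models are selected per candidate DNA index (tumour DNA
#' content relative to diploid); each candidate rescales the locus total
#' copy number consistently. Refits the clustering under each candidate
#' and reports whether the cluster counts agree qualitatively (within
#' +/- 1). Candidates pushing purity toward 0 produce clamp-dominated
#' prevalence estimates and are flagged unreliable.
#'
#' @param obs observation data.frame (see [estimate_prevalence()]).
#' @param dna_indices numeric vector (typically 3 values, 1 = diploid).
#' @param ... passed to [cluster_prevalences()].
#' @return list with `fits` (one `clone_fit` per candidate),
#'   `n_clusters`, `qualitative_agreement`, `unreliable` flags.
#' @export
sensitivity_over_dna_index <- function(obs, dna_indices, ...) {
  fits <- lapply(dna_indices, function(di) {
    o <- obs
    o$total_cn <- pmax(round(o$total_cn * di), 1L)
    o$vaf <- NULL; o$prevalence <- NULL; o$clamped <- NULL
    o <- estimate_prevalence(o)
    fit <- cluster_prevalences(o, ...)
    fit$clamp_fraction <- mean(o$clamped)
    fit
  })
  k <- vapply(fits, function(f) f$n_clusters, integer(1))
  list(fits = fits, dna_indices = dna_indices, n_clusters = k,
       qualitative_agreement = max(k) - min(k) <= 1,
       unreliable = vapply(fits, function(f) f$clamp_fraction > 0.5,
                           logical(1)))
}
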