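# Two-component Dirichlet-multinomial mixture over edit-distance counts,
# fit by (penalized, MAP) expectation-maximization.
#
# Per association g with p_g candidate SNPs:
#   V_g ~ Bernoulli(gamma)                        causal indicator
#   Theta_g | Pi_g ~ Dirichlet(Pi_g)              per-SNP causal probabilities
#   Z_g | V_g = 1 ~ Multinomial(1, Theta_g)       causal SNP; Z_g = 0 if V_g=0
#   causal:  n_g ~ Mult(5, a1), m_g ~ Mult(3, b1) (Y~ vs R~ of the causal SNP)
#   null:    n0_g ~ Mult(5, a0), m0_g ~ Mult(3, b0) (Y~ vs B~)
#
# Counts are tallied over the 5 classical and 3 wild-derived strains
# separately. The M-step adds fixed pseudocounts lambda_i * p_g per gene to
# each of the four count sums, tilting a/b toward low edit distances.

log_clamp <- function(p) log(pmax(p, 1e-300))

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) <= 0) x <- alpha / sum(alpha) else x <- x / sum(x)
  x
}

#' Assemble model-ready data from association instances
#'
#' Trinarizes the DO allelic-effect vector (Y), each candidate's
#' genotype-effect pattern (rows of E selected by the candidate), and the
#' founder expression vector (B), then computes the causal edit-distance
#' counts (Y~ vs R~, one row per candidate) and the null counts (Y~ vs B~,
#' one row per gene).
#'
#' @param instances List of `"eqtl_instance"` objects with candidates
#'   attached ([assemble_instances()]).
#' @param expr Founder expression matrix from [read_founder_expression()]
#'   (genes x 8), or `NULL` (the null pattern B~ is then all-zero).
#' @param panel A [strain_panel()].
#' @param cutoff Trinarization cutoff (default 0.2).
#' @param effect_alpha Significance level for genotype-effect trinarization
#'   (default 0.05).
#' @return An object of class `"model_data"`: `gene_id` (G), `p` (G),
#'   `gene_index` (K = sum p_g, mapping candidate row to gene), `snp_id`,
#'   `snp_pos`, `dist_to_marker`, `dist_to_promoter` (K), `counts` (K x 6
#'   matrix n0,n1,n2,m0,m1,m2), `null_counts` (G x 6), `y_tri` (G x 8),
#'   `r_tri` (K x 8), `b_tri` (G x 8).
#' @export
build_model_data <- function(instances, expr = NULL, panel = strain_panel(),
                             cutoff = 0.2, effect_alpha = 0.05) {
  G <- length(instances)
  stopifnot(G >= 1L)
  p <- vapply(instances, function(x) nrow(x$candidates), integer(1))
  gene_index <- rep(seq_len(G), p)
  gcols <- paste0("geno_", panel$strains)

  # simulated instances carry the trinary pattern directly (materialized
  # patterns may have a nonzero reference code, unreachable by trinarization)
  y_tri <- t(vapply(instances, function(x) {
    if (!is.null(x$effects_tri)) as.integer(x$effects_tri)
    else trinarize_effects(x$effects, panel, cutoff)
  }, integer(8)))
  b_tri <- t(vapply(instances, function(x) {
    if (!is.null(expr) && x$gene_id %in% rownames(expr))
      trinarize_effects(expr[x$gene_id, ], panel, cutoff)
    else integer(8)
  }, integer(8)))

  # vectorized trinarize_genotype_effects: code = sign(effect) if
  # significant else 0, broadcast over alt-allele carriage
  r_tri <- do.call(rbind, lapply(instances, function(x) {
    cand <- x$candidates
    code <- ifelse(cand$effect_pvalue < effect_alpha, sign(cand$effect), 0)
    geno <- as.matrix(cand[gcols])
    m <- geno * code
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m
  }))

  counts <- edit_count_matrix(y_tri[gene_index, , drop = FALSE], r_tri, panel)
  null_counts <- edit_count_matrix(y_tri, b_tri, panel)

  structure(list(
    gene_id = vapply(instances, `[[`, character(1), "gene_id"),
    p = p,
    gene_index = gene_index,
    snp_id = unlist(lapply(instances, function(x) x$candidates$snp_id),
                    use.names = FALSE),
    snp_pos = unlist(lapply(instances, function(x) x$candidates$pos),
                     use.names = FALSE),
    dist_to_marker = unlist(lapply(instances,
                                   function(x) x$candidates$dist_to_marker),
                            use.names = FALSE),
    dist_to_promoter = unlist(lapply(instances,
                                     function(x) x$candidates$dist_to_promoter),
                              use.names = FALSE),
    counts = counts,
    null_counts = null_counts,
    y_tri = y_tri, r_tri = r_tri, b_tri = b_tri),
    class = "model_data")
}

# Row-wise edit-distance counts for matrices of trinary codes (rows paired).
edit_count_matrix <- function(Y, R, panel = strain_panel()) {
  d <- abs(Y - R)
  dn <- d[, panel$classical_idx, drop = FALSE]
  dw <- d[, panel$wild_idx, drop = FALSE]
  out <- cbind(n0 = rowSums(dn == 0), n1 = rowSums(dn == 1),
               n2 = rowSums(dn == 2), m0 = rowSums(dw == 0),
               m1 = rowSums(dw == 1), m2 = rowSums(dw == 2))
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

#' Log-likelihood of edit-distance counts under the causal component
#'
#' `sum_i n_i log a1_i + sum_i m_i log b1_i` with the convention
#' `0 * log 0 = 0`; returns `-Inf` when a zero-probability cell has a
#' positive count.
#'
#' @param counts An `"edit_counts"` object ([edit_distance_counts()]) or a
#'   list with integer triples `n` and `m`.
#' @param a1,b1 Probability triples (sum to 1) for the classical and wild
#'   counts.
#' @return Scalar log-likelihood.
#' @export
causal_loglik <- function(counts, a1, b1) {
  cc <- c(counts$n, counts$m)
  pp <- c(a1, b1)
  if (any(cc > 0 & pp == 0)) return(-Inf)
  sum(ifelse(cc > 0, cc * log(pp), 0))
}

#' Log-likelihood of null edit-distance counts
#'
#' Same multinomial kernel as [causal_loglik()] applied to the null pairing
#' (DO pattern vs founder-expression pattern) with parameters `(a0, b0)`.
#' The mixture weight `(1 - gamma)` is applied in the E-step, not here.
#'
#' @param counts0 Null `"edit_counts"`.
#' @param a0,b0 Null probability triples.
#' @return Scalar log-likelihood.
#' @export
null_loglik <- function(counts0, a0, b0) causal_loglik(counts0, a0, b0)

# Internal: per-row causal and per-gene null log-likelihood under params.
loglik_rows <- function(data, params) {
  list(ll1 = unname(drop(data$counts %*%
                           log_clamp(c(params$a1, params$b1)))),
       ll0 = unname(drop(data$null_counts %*%
                           log_clamp(c(params$a0, params$b0)))))
}

#' E-step: posterior responsibilities over (V, Z)
#'
#' For each gene the states are the null (V = 0) and one state per candidate
#' (V = 1, Z = k). Unnormalized posteriors are
#' `gamma * theta_k * L1_k` and `(1 - gamma) * L0`, normalized per gene in
#' log space with max-subtraction. If every state has zero likelihood the
#' responsibilities are set uniform with a warning.
#'
#' @param data A `"model_data"` object.
#' @param params Parameter list with `a0`, `a1`, `b0`, `b1` (probability
#'   triples), `gamma` in (0,1), and `theta` (stacked per-gene simplexes,
#'   length K).
#' @param hard If `TRUE`, responsibilities are collapsed onto the per-gene
#'   maximum-posterior state (hard EM).
#' @return List of class `"responsibilities"`: `w` (K), `w_null` (G),
#'   `v_hat` (G).
#' @export
estep <- function(data, params, hard = FALSE) {
  ll <- loglik_rows(data, params)
  gi <- data$gene_index
  G <- length(data$p)
  log_w <- log_clamp(params$gamma) + log_clamp(params$theta) + ll$ll1
  log_null <- log_clamp(1 - params$gamma) + ll$ll0
  gmax <- as.numeric(tapply(log_w, gi, max))
  M <- pmax(gmax, log_null)
  bad <- !is.finite(M)
  if (any(bad)) {
    warning(sprintf(
      "%d gene(s) with zero likelihood in every component; uniform responsibilities used",
      sum(bad)), call. = FALSE)
    M[bad] <- 0
    log_null[bad] <- 0
    log_w[gi %in% which(bad)] <- 0
  }
  w_rel <- exp(log_w - M[gi])
  null_rel <- exp(log_null - M)
  denom <- unname(drop(rowsum(w_rel, gi))) + null_rel
  w <- unname(w_rel / denom[gi])
  w_null <- unname(null_rel / denom)
  if (hard) {
    # argmax imputation; null wins ties with candidates, the first candidate
    # achieving the max wins ties among candidates
    wmax <- as.numeric(tapply(w, gi, max))
    pick_null <- w_null >= wmax
    idx <- which(w == wmax[gi])
    keep <- idx[!duplicated(gi[idx])]
    w <- numeric(length(w))
    w[keep] <- 1
    w[gi %in% which(pick_null)] <- 0
    w_null <- as.numeric(pick_null)
  }
  structure(list(w = w, w_null = w_null,
                 v_hat = 1 - w_null),
            class = "responsibilities")
}

#' M-step: multinomial MLEs with pseudocounts, MAP Theta, and gamma
#'
#' Count sums weighted by the responsibilities receive fixed pseudocounts
#' `lambda_i * p_g` per gene (so `lambda * sum(p_g)` in total per cell);
#' `a1 = N / N_total` etc. The Dirichlet MAP update for the causal
#' probabilities substitutes the soft responsibilities for `Z_{g,k} V_g`:
#' `theta_k = (pi_k + w_k - 1) / (sum_k (pi_k + w_k) - p_g)`, with a uniform
#' fallback when the denominator vanishes (only reachable under a flat
#' prior). `gamma` is the mean posterior causal probability, clipped away
#' from \{0, 1\}.
#'
#' @param data A `"model_data"` object.
#' @param resp Responsibilities from [estep()].
#' @param pi Stacked prior weights (length K) from the gene priors.
#' @param lambda Pseudocount triple (default `c(0.1, 0.01, 0)`).
#' @return Parameter list (`a0`, `a1`, `b0`, `b1`, `gamma`, `theta`).
#' @export
mstep <- function(data, resp, pi, lambda = c(0.1, 0.01, 0)) {
  gi <- data$gene_index
  P <- sum(data$p)
  caus <- colSums(data$counts * resp$w)
  null <- colSums(data$null_counts * resp$w_null)
  N <- caus[1:3] + lambda * P
  M <- caus[4:6] + lambda * P
  N0 <- null[1:3] + lambda * P
  M0 <- null[4:6] + lambda * P
  num <- pmax(pi + resp$w - 1, 0)
  sumpi <- drop(rowsum(pi, gi))
  den <- sumpi + resp$v_hat - data$p
  theta <- numeric(P)
  ok <- den > 1e-12
  theta[ok[gi]] <- (num / den[gi])[ok[gi]]
  if (any(!ok)) {
    warning("degenerate MAP denominator; uniform theta used", call. = FALSE)
    theta[!ok[gi]] <- (1 / data$p[gi])[!ok[gi]]
  }
  list(a1 = unname(N / sum(N)), a0 = unname(N0 / sum(N0)),
       b1 = unname(M / sum(M)), b0 = unname(M0 / sum(M0)),
       gamma = min(max(mean(resp$v_hat), 1e-6), 1 - 1e-6),
       theta = theta)
}

#' Penalized observed-data objective
#'
#' Monitors EM convergence and compares restarts:
#' `sum_g log(gamma * sum_k theta_k L1_k + (1-gamma) L0_g)`
#' plus the log Dirichlet prior density of each `Theta_g` at its prior
#' weights and the pseudocount regularizers
#' `sum_i lambda_i * P * (log a0_i + log a1_i + log b0_i + log b1_i)`.
#' Each EM iteration is guaranteed not to decrease this quantity.
#'
#' @inheritParams estep
#' @param pi Stacked prior weights (length K).
#' @param lambda Pseudocount triple.
#' @return Scalar objective value.
#' @export
model_objective <- function(data, params, pi, lambda = c(0.1, 0.01, 0)) {
  ll <- loglik_rows(data, params)
  gi <- data$gene_index
  log_w <- log_clamp(params$gamma) + log_clamp(params$theta) + ll$ll1
  log_null <- log_clamp(1 - params$gamma) + ll$ll0
  M <- pmax(as.numeric(tapply(log_w, gi, max)), log_null)
  obs <- sum(M + log(drop(rowsum(exp(log_w - M[gi]), gi)) +
                       exp(log_null - M)))
  sumpi <- drop(rowsum(pi, gi))
  lgsum <- drop(rowsum(lgamma(pi), gi))
  dir_term <- sum(lgamma(sumpi) - lgsum) +
    sum(ifelse(pi > 1, (pi - 1) * log_clamp(params$theta), 0))
  ab <- rbind(params$a0, params$a1, params$b0, params$b1)
  pen <- sum(vapply(1:3, function(i) {
    if (lambda[i] == 0) 0 else lambda[i] * sum(data$p) *
      sum(log_clamp(ab[, i]))
  }, numeric(1)))
  obs + dir_term + pen
}

#' Fit control parameters
#'
#' @param restarts Number of random EM restarts (default 10).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Relative objective-change convergence tolerance (default 1e-8).
#' @param lambda Pseudocount triple (default `c(0.1, 0.01, 0)`).
#' @param seed Integer seed; the fit is deterministic given it.
#' @param em_mode `"soft"` (posterior expectations, default) or `"hard"`
#'   (argmax imputation) for the latent indicators.
#' @return A list of class `"fit_control"`.
#' @export
fit_control <- function(restarts = 10, max_iter = 500, tol = 1e-8,
                        lambda = c(0.1, 0.01, 0), seed = 1,
                        em_mode = c("soft", "hard")) {
  stopifnot(restarts >= 1, max_iter >= 1, tol > 0,
            length(lambda) == 3, all(lambda >= 0))
  structure(list(restarts = restarts, max_iter = max_iter, tol = tol,
                 lambda = lambda, seed = as.integer(seed),
                 em_mode = match.arg(em_mode)),
            class = "fit_control")
}

init_params <- function(data, pi) {
  sumpi <- drop(rowsum(pi, data$gene_index))
  list(a1 = rdirichlet1(40 * c(0.7, 0.2, 0.1)),
       b1 = rdirichlet1(40 * c(0.7, 0.2, 0.1)),
       a0 = rdirichlet1(40 * rep(1 / 3, 3)),
       b0 = rdirichlet1(40 * rep(1 / 3, 3)),
       gamma = stats::runif(1, 0.4, 0.6),
       theta = pi / sumpi[data$gene_index])
}

#' Fit the mixture model by multi-restart EM
#'
#' Alternates [estep()] and [mstep()] until the relative change of
#' [model_objective()] falls below `tol` or `max_iter` is reached, for each
#' of `restarts` random initializations (causal triples initialized near
#' (0.7, 0.2, 0.1), null triples near uniform, theta proportional to the
#' prior). The restart with the highest final objective wins; exact ties
#' (within 1e-12) keep the lowest restart index. Deterministic given
#' `control$seed`.
#'
#' @param data A `"model_data"` object.
#' @param priors List of `"gene_prior"` objects aligned with the genes, or
#'   `NULL` for flat priors.
#' @param control A [fit_control()].
#' @return An object of class `"finemap_fit"`: `params`, `resp`
#'   (final responsibilities), `objective`, `objective_trace` (winning
#'   restart), `restart_objectives`, `restart_traces`, `n_restarts`,
#'   `best_restart`, `seed`, `converged`, `n_iter`, and the stacked prior
#'   `pi`.
#' @export
fit_model <- function(data, priors = NULL, control = fit_control()) {
  pi <- if (is.null(priors)) rep(1, sum(data$p)) else
    unlist(lapply(priors, `[[`, "pi"), use.names = FALSE)
  stopifnot(length(pi) == sum(data$p))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(control$seed)
  hard <- control$em_mode == "hard"
  best <- NULL
  restart_obj <- numeric(control$restarts)
  all_traces <- vector("list", control$restarts)
  for (r in seq_len(control$restarts)) {
    params <- init_params(data, pi)
    trace <- numeric(0)
    obj_prev <- -Inf
    converged <- FALSE
    iter <- 0L
    while (iter < control$max_iter) {
      iter <- iter + 1L
      resp <- estep(data, params, hard = hard)
      params <- mstep(data, resp, pi, control$lambda)
      obj <- model_objective(data, params, pi, control$lambda)
      trace <- c(trace, obj)
      if (is.finite(obj) && is.finite(obj_prev) &&
          abs(obj - obj_prev) <= control$tol * (abs(obj_prev) + 1e-12)) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }
    resp <- estep(data, params, hard = hard)  # responsibilities at the optimum
    restart_obj[r] <- obj
    all_traces[[r]] <- trace
    if (is.null(best) || obj > best$objective + 1e-12) {
      best <- list(params = params, resp = resp, objective = obj,
                   objective_trace = trace, best_restart = r,
                   converged = converged, n_iter = iter)
    }
  }
  if (!best$converged)
    warning("EM did not converge within max_iter for the best restart",
            call. = FALSE)
  structure(c(best,
              list(restart_objectives = restart_obj,
                   restart_traces = all_traces,
                   n_restarts = control$restarts, seed = control$seed,
                   pi = pi)),
            class = "finemap_fit")
}

#' @export
print.finemap_fit <- function(x, ...) {
  cat("Dirichlet-multinomial mixture fit\n")
  cat(sprintf("  genes: %d, candidates: %d\n",
              length(x$resp$v_hat), length(x$resp$w)))
  cat(sprintf("  gamma = %.4f\n", x$params$gamma))
  cat(sprintf("  a1 = (%s)   b1 = (%s)\n",
              paste(sprintf("%.3f", x$params$a1), collapse = ", "),
              paste(sprintf("%.3f", x$params$b1), collapse = ", ")))
  cat(sprintf("  a0 = (%s)   b0 = (%s)\n",
              paste(sprintf("%.3f", x$params$a0), collapse = ", "),
              paste(sprintf("%.3f", x$params$b0), collapse = ", ")))
  cat(sprintf("  objective = %.4f (restart %d/%d, %s in %d iterations)\n",
              x$objective, x$best_restart, x$n_restarts,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Write a fitted model as JSON
#'
#' @param fit A `"finemap_fit"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(a0 = fit$params$a0, a1 = fit$params$a1,
         b0 = fit$params$b0, b1 = fit$params$b1,
         gamma = fit$params$gamma, seed = fit$seed,
         objective = fit$objective, converged = fit$converged,
         n_iter = fit$n_iter),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
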