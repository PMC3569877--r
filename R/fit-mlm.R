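#' Control parameters for the multilevel fit
#'
#' @param max_iter Iteration cap for the scoring loop.
#' @param tol Relative deviance-change convergence tolerance.
#' @param score_tol Score-norm threshold reported (not enforced) at exit.
#' @param max_halvings Maximum step-halvings per iteration when an update
#'   leaves the positive-definite region or increases the deviance.
#' @param verbose Print per-iteration deviance.
#' @return A list of class `mlm_control`.
#' @export
mlm_control <- function(max_iter = 200L, tol = 1e-8, score_tol = 1e-3,
                        max_halvings = 30L, verbose = FALSE) {
  structure(
    list(
      max_iter = as.integer(max_iter), tol = tol, score_tol = score_tol,
      max_halvings = as.integer(max_halvings), verbose = isTRUE(verbose)
    ),
    class = "mlm_control"
  )
}

# ---- internal: parameter bookkeeping ---------------------------------------

# unique-entry (vech) pairs of an M x M symmetric matrix, row-major upper
# triangle: (1,1),(1,2),...,(1,M),(2,2),...
vech_pairs <- function(terms) {
  M <- length(terms)
  a <- rep(seq_len(M), times = M - seq_len(M) + 1L)
  b <- unlist(lapply(seq_len(M), function(i) i:M))
  tibble::tibble(
    a = a, b = b,
    name = paste(terms[a], terms[b], sep = "||")
  )
}

# M^2 x P matrix mapping vech coordinates to vec(E_ab) columns, where E_ab is
# the symmetric basis matrix (ones at (a,b) and (b,a)).
vech_expander <- function(M, pairs) {
  U <- matrix(0, M * M, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$a[i]; b <- pairs$b[i]
    U[(b - 1L) * M + a, i] <- 1
    U[(a - 1L) * M + b, i] <- 1  # same cell when a == b (stays 1)
  }
  U
}

# occasion-level (level-1) parameter index: one variance per response plus one
# covariance per unordered response pair
rpar_index <- function(responses) {
  n <- length(responses)
  vars <- tibble::tibble(
    name = paste0("resid_var:", responses),
    type = "var", r1 = seq_len(n), r2 = seq_len(n)
  )
  if (n > 1L) {
    cmb <- utils::combn(n, 2L)
    covs <- tibble::tibble(
      name = paste0("resid_cov:", responses[cmb[1L, ]], ":", responses[cmb[2L, ]]),
      type = "cov", r1 = cmb[1L, ], r2 = cmb[2L, ]
    )
    vars <- dplyr::bind_rows(vars, covs)
  }
  vars
}

build_R_matrix <- function(rtheta, rpar, responses) {
  n <- length(responses)
  R <- matrix(0, n, n, dimnames = list(responses, responses))
  for (i in seq_len(nrow(rpar))) {
    R[rpar$r1[i], rpar$r2[i]] <- rtheta[i]
    R[rpar$r2[i], rpar$r1[i]] <- rtheta[i]
  }
  R
}

extract_R_theta <- function(R, rpar) {
  vapply(seq_len(nrow(rpar)), function(i) R[rpar$r1[i], rpar$r2[i]], numeric(1))
}

# ---- internal: data assembly ----------------------------------------------

# Builds per-individual stacked vectors/design matrices. Rows are ordered by
# response (spec order) then time within response. Occasions of different
# responses are matched on exact time equality (round times first if needed).
assemble_individuals <- function(data, spec) {
  data <- validate_long_data(data, spec)
  specs <- spec$specs
  responses <- names(specs)
  idx <- spec$ranef
  M <- nrow(idx)
  for (cv in unique(unlist(spec$covariates))) {
    if (!is.numeric(data[[cv]])) {
      abort(sprintf(
        "covariate '%s' must be numeric; expand categorical covariates to indicator columns first.",
        cv
      ))
    }
  }
  data$..resp_i <- match(data$response, responses)
  data <- dplyr::arrange(data, .data$id, .data$..resp_i, .data$time)

  # fixed-effect design, one block of columns per response
  fe_names <- unlist(purrr::imap(specs, function(s, r) {
    paste0(r, ":", c("intercept", paste0("slope", seq_len(n_splines(s))), spec$covariates[[r]]))
  }), use.names = FALSE)
  Fdim <- length(fe_names)
  Xall <- matrix(0, nrow(data), Fdim, dimnames = list(NULL, fe_names))
  Zall <- matrix(0, nrow(data), M, dimnames = list(NULL, idx$term))
  col_off <- 0L
  for (r in seq_along(responses)) {
    s <- specs[[r]]
    rows <- which(data$..resp_i == r)
    B <- spline_basis(s, data$time[rows])
    m <- ncol(B)
    covs <- spec$covariates[[responses[r]]]
    ncov <- length(covs)
    Xall[rows, col_off + 1L] <- 1
    Xall[rows, col_off + 1L + seq_len(m)] <- B
    if (ncov) {
      Xall[rows, col_off + 1L + m + seq_len(ncov)] <-
        as.matrix(data[rows, covs, drop = FALSE])
    }
    zcols <- which(idx$response == responses[r])
    Zall[rows, zcols[1L]] <- 1
    Zall[rows, zcols[-1L]] <- B
    col_off <- col_off + 1L + m + ncov
  }

  ids <- unique(data$id)
  rows_by_id <- split(seq_len(nrow(data)), factor(data$id, levels = ids))
  individuals <- purrr::map(rows_by_id, function(rr) {
    ri <- data$..resp_i[rr]
    tt <- data$time[rr]
    # occasion matches: row pairs of distinct responses sharing a time
    pair_i <- integer(0); pair_j <- integer(0)
    if (length(unique(ri)) > 1L) {
      for (tv in unique(tt[duplicated(tt)])) {
        at <- which(tt == tv)
        if (length(at) > 1L) {
          cmb <- utils::combn(length(at), 2L)
          keep <- ri[at[cmb[1L, ]]] != ri[at[cmb[2L, ]]]
          pair_i <- c(pair_i, at[cmb[1L, keep]])
          pair_j <- c(pair_j, at[cmb[2L, keep]])
        }
      }
    }
    list(
      y = data$value[rr],
      X = Xall[rr, , drop = FALSE],
      Z = Zall[rr, , drop = FALSE],
      resp = ri, time = tt,
      pair_i = pair_i, pair_j = pair_j
    )
  })
  list(
    individuals = individuals, ids = ids, responses = responses,
    fe_names = fe_names, M = M, n_obs = nrow(data),
    fingerprint = data_fingerprint(data)
  )
}

data_fingerprint <- function(data) {
  c(
    n_rows = nrow(data), n_ids = length(unique(data$id)),
    value_sum = sum(data$value), time_sum = sum(data$time)
  )
}

# occasion-level covariance matrix for one individual, from the response
# index per row and matched-occasion pairs
build_Rk <- function(ind, R) {
  r <- length(ind$y)
  Rk <- diag(diag(R)[ind$resp], nrow = r)
  if (length(ind$pair_i)) {
    cv <- R[cbind(ind$resp[ind$pair_i], ind$resp[ind$pair_j])]
    Rk[cbind(ind$pair_i, ind$pair_j)] <- cv
    Rk[cbind(ind$pair_j, ind$pair_i)] <- cv
  }
  Rk
}

# level-1 structure matrix S_a for R-parameter a (dense, r x r)
build_Sk <- function(ind, rpar_row) {
  r <- length(ind$y)
  S <- matrix(0, r, r)
  if (rpar_row$type == "var") {
    d <- which(ind$resp == rpar_row$r1)
    if (length(d)) S[cbind(d, d)] <- 1
  } else {
    if (length(ind$pair_i)) {
      sel <- (ind$resp[ind$pair_i] == rpar_row$r1 & ind$resp[ind$pair_j] == rpar_row$r2) |
        (ind$resp[ind$pair_i] == rpar_row$r2 & ind$resp[ind$pair_j] == rpar_row$r1)
      if (any(sel)) {
        S[cbind(ind$pair_i[sel], ind$pair_j[sel])] <- 1
        S[cbind(ind$pair_j[sel], ind$pair_i[sel])] <- 1
      }
    }
  }
  S
}

# ---- internal: likelihood machinery ----------------------------------------

# One sweep over individuals at (G, R): returns -2 loglik given beta, or the
# GLS quantities when beta is NULL. Returns NULL if any V_k is not PD.
sweep_deviance <- function(asm, G, R, beta) {
  dev <- 0
  for (ind in asm$individuals) {
    Vk <- ind$Z %*% G %*% t(ind$Z) + build_Rk(ind, R)
    ch <- tryCatch(chol(Vk), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    e <- ind$y - drop(ind$X %*% beta)
    u <- backsolve(ch, e, transpose = TRUE)
    dev <- dev + 2 * sum(log(diag(ch))) + sum(u * u) + length(e) * log(2 * pi)
  }
  dev
}

gls_beta <- function(asm, G, R) {
  Fdim <- length(asm$fe_names)
  XtPX <- matrix(0, Fdim, Fdim)
  XtPy <- numeric(Fdim)
  chols <- vector("list", length(asm$individuals))
  for (i in seq_along(asm$individuals)) {
    ind <- asm$individuals[[i]]
    Vk <- ind$Z %*% G %*% t(ind$Z) + build_Rk(ind, R)
    ch <- tryCatch(chol(Vk), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    chols[[i]] <- ch
    Xs <- backsolve(ch, ind$X, transpose = TRUE)
    ys <- backsolve(ch, ind$y, transpose = TRUE)
    XtPX <- XtPX + crossprod(Xs)
    XtPy <- XtPy + drop(crossprod(Xs, ys))
  }
  beta <- tryCatch(solve(XtPX, XtPy), error = function(e) {
    abort("fixed-effects design is singular; check for collinear covariates.")
  })
  list(beta = drop(beta), XtPX = XtPX, chols = chols)
}

# Score and expected information for all variance parameters (full vech of G
# followed by occasion-level parameters), plus the deviance, at (G, R, beta).
score_info <- function(asm, G, R, beta, chols, U, rpar) {
  M <- asm$M
  nR <- nrow(rpar)
  Ksum <- matrix(0, M * M, M * M)
  svec <- numeric(M * M)
  Hsum <- replicate(nR, matrix(0, M, M), simplify = FALSE)
  score_R <- numeric(nR)
  info_RR <- matrix(0, nR, nR)
  dev <- 0
  for (i in seq_along(asm$individuals)) {
    ind <- asm$individuals[[i]]
    ch <- chols[[i]]
    e <- ind$y - drop(ind$X %*% beta)
    u <- backsolve(ch, e, transpose = TRUE)
    dev <- dev + 2 * sum(log(diag(ch))) + sum(u * u) + length(e) * log(2 * pi)
    p <- backsolve(ch, u)                       # V^{-1} e
    ZV <- backsolve(ch, backsolve(ch, ind$Z, transpose = TRUE))  # V^{-1} Z
    C <- crossprod(ind$Z, ZV)
    w <- drop(crossprod(ind$Z, p))
    Ksum <- Ksum + (C %x% C)
    svec <- svec + (w %x% w) - as.vector(C)
    if (nR) {
      Vinv <- chol2inv(ch)
      Ts <- vector("list", nR)
      for (a in seq_len(nR)) {
        Sa <- build_Sk(ind, rpar[a, ])
        Ts[[a]] <- Vinv %*% Sa
        score_R[a] <- score_R[a] + drop(crossprod(p, Sa %*% p)) - sum(Vinv * Sa)
        Hsum[[a]] <- Hsum[[a]] + crossprod(ZV, Sa %*% ZV)
      }
      for (a in seq_len(nR)) {
        for (b in a:nR) {
          v <- sum(Ts[[a]] * t(Ts[[b]]))
          info_RR[a, b] <- info_RR[a, b] + v
          info_RR[b, a] <- info_RR[a, b]
        }
      }
    }
  }
  score_G <- 0.5 * drop(crossprod(U, svec))
  info_GG <- 0.5 * crossprod(U, Ksum %*% U)
  info_GR <- matrix(0, ncol(U), nR)
  for (a in seq_len(nR)) {
    info_GR[, a] <- 0.5 * drop(crossprod(U, as.vector(Hsum[[a]])))
  }
  list(
    score = c(score_G, 0.5 * score_R),
    info = rbind(cbind(info_GG, info_GR), cbind(t(info_GR), 0.5 * info_RR)),
    deviance = dev
  )
}

# ---- log-likelihood ---------------------------------------------------------

#' Log-likelihood of the multivariate spline multilevel model
#'
#' Evaluates the exact marginal log-likelihood: the sum over individuals of
#' the multivariate-normal log-density of the individual's stacked
#' observation vector, with mean `X_k beta` and covariance
#' `Z_k G Z_k' + R_k`, where `Z_k` stacks an intercept indicator and the
#' spline basis per response and `R_k` carries the occasion-level covariance
#' (cross-response covariance only for occasions where both responses are
#' observed at the same time).
#'
#' A non-positive-definite covariance is not an error: the function returns
#' `-Inf` so that an optimiser probing an invalid point can recover.
#'
#' @param data Long-format data (see [validate_long_data()]).
#' @param spec An [mlm_spec()].
#' @param fixef Named numeric vector of fixed effects in the design order
#'   (`response:intercept`, `response:slope1..m`, covariates per response).
#' @param G M x M symmetric individual-level covariance matrix (rows ordered
#'   as [ranef_index()]).
#' @param R Occasion-level covariance matrix across responses (n_resp x
#'   n_resp; a 1 x 1 matrix or scalar for univariate models).
#' @return The log-likelihood (scalar), or `-Inf` if any individual's
#'   marginal covariance is not positive-definite.
#' @export
mlm_loglik <- function(data, spec, fixef, G, R) {
  if (!inherits(spec, "mlm_spec")) spec <- mlm_spec(spec)
  asm <- assemble_individuals(data, spec)
  if (is.null(dim(R))) R <- matrix(R, 1L, 1L)
  beta <- align_fixef(fixef, asm$fe_names)
  dev <- sweep_deviance(asm, G, R, beta)
  if (is.null(dev)) return(-Inf)
  -dev / 2
}

align_fixef <- function(fixef, fe_names) {
  if (!is.null(names(fixef)) && all(fe_names %in% names(fixef))) {
    unname(fixef[fe_names])
  } else if (length(fixef) == length(fe_names)) {
    unname(fixef)
  } else {
    abort(sprintf(
      "fixed effects must be length %d (or named): %s",
      length(fe_names), paste(fe_names, collapse = ", ")
    ))
  }
}

# ---- fitting ----------------------------------------------------------------

#' Fit the multivariate linear-spline multilevel model by maximum likelihood
#'
#' Maximises the marginal likelihood over the fixed effects, the
#' individual-level random-effect covariance matrix `G` and the
#' occasion-level covariance `R`, with any covariances listed in the
#' constraint set held exactly at zero. Estimation is Fisher scoring on the
#' free unique (co)variance entries with the fixed effects profiled out by
#' generalised least squares at each step; steps are halved whenever an
#' update leaves the positive-definite region or increases the deviance.
#' The free entries of `G` are optimised directly (not through a Cholesky
#' factor), which is what makes exact entry-wise zeros representable.
#'
#' The sampling covariance `Gamma` of the unique entries of `G` is the
#' corresponding block of the inverse expected (Fisher) information of all
#' free (co)variance parameters at the optimum, on the raw covariance scale;
#' rows and columns of constrained entries are zero.
#'
#' @param data Long-format data with columns `id`, `time`, `response`,
#'   `value` and any covariate columns.
#' @param spec An [mlm_spec()] (or a list of [spline_spec()]s, promoted with
#'   no covariates).
#' @param constraints Optional [constraint_set] overriding `spec$constraints`.
#' @param init Optional list with any of `fixef`, `G`, `R` as starting
#'   values; defaults come from per-response ordinary least squares on the
#'   spline basis with a scaled-diagonal `G`. For hard problems, fit a
#'   simpler (more constrained or univariate) model first and pass its
#'   estimates here.
#' @param control An [mlm_control()].
#' @return An object of class `mlm_fit` with elements `fixef` (tibble),
#'   `G`, `R`, `deviance`, `gamma` (sampling covariance of the unique
#'   entries of `G`), `gamma_all` (including occasion-level parameters),
#'   `vcov_fixef`, `convergence`, `n_individuals`, `spec`, `constraints`,
#'   `data`.
#' @examples
#' wt <- spline_spec("weight", 8, c(18, 29), 44)
#' sim <- simulate_growth(generator_spec(
#'   n_individuals = 80, specs = list(wt),
#'   fixed_effects = list(weight = c(62, 0.3, 0.5, 0.4)),
#'   G_true = diag(c(25, 0.02, 0.02, 0.02)), R_true = 1.2, seed = 1
#' ))
#' fit <- fit_mlm(sim$data, mlm_spec(list(wt)))
#' glance(fit)
#' @export
fit_mlm <- function(data, spec, constraints = NULL, init = NULL,
                    control = mlm_control()) {
  if (!inherits(spec, "mlm_spec")) spec <- mlm_spec(spec)
  constraints <- constraints %||% spec$constraints
  if (!is.null(constraints)) {
    constraints <- validate_constraints(constraints, spec$ranef)
  }
  asm <- assemble_individuals(data, spec)
  M <- asm$M
  responses <- asm$responses
  for (r in responses) {
    if (!any(vapply(asm$individuals, function(ind) any(ind$resp == match(r, responses)), logical(1)))) {
      abort(sprintf("response '%s' is never observed.", r))
    }
  }
  if (max(vapply(asm$individuals, function(ind) length(ind$y), numeric(1))) < M) {
    warn(paste(
      "every individual has fewer occasions than the random-effect dimension;",
      "the model relies entirely on pooling across individuals."
    ))
  }

  pairs <- vech_pairs(spec$ranef$term)
  U <- vech_expander(M, pairs)
  rpar <- rpar_index(responses)
  constrained <- constrained_mask(pairs, spec$ranef$term, constraints)
  free_idx <- c(which(!constrained), nrow(pairs) + seq_len(nrow(rpar)))

  st <- default_start(asm, spec, init)
  G <- zero_constrained(st$G, pairs, constrained, spec$ranef$term)
  R <- st$R

  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  halvings_total <- 0L
  score_norm <- NA_real_
  gls <- gls_beta(asm, G, R)
  if (is.null(gls)) abort("starting covariance values are not positive-definite.")

  repeat {
    iter <- iter + 1L
    si <- score_info(asm, G, R, gls$beta, gls$chols, U, rpar)
    dev_cur <- si$deviance
    if (control$verbose) {
      inform(sprintf("iter %3d deviance %.6f", iter, dev_cur))
    }
    score_free <- si$score[free_idx]
    info_free <- si$info[free_idx, free_idx, drop = FALSE]
    delta <- tryCatch(solve(info_free, score_free), error = function(e) {
      MASS::ginv(info_free) %*% score_free
    })
    delta <- drop(delta)
    score_norm <- sqrt(sum(score_free^2))

    if (is.finite(dev_old) &&
        abs(dev_old - dev_cur) < control$tol * (abs(dev_cur) + 1)) {
      converged <- TRUE
      dev_old <- dev_cur
      break
    }

    theta <- c(G_to_vech(G, pairs), extract_R_theta(R, rpar))
    step <- 1
    ok <- FALSE
    for (h in seq_len(control$max_halvings)) {
      theta_new <- theta
      theta_new[free_idx] <- theta[free_idx] + step * delta
      G_new <- vech_to_G(theta_new[seq_len(nrow(pairs))], pairs, M, spec$ranef$term)
      R_new <- build_R_matrix(
        theta_new[nrow(pairs) + seq_len(nrow(rpar))], rpar, responses
      )
      gls_new <- gls_beta(asm, G_new, R_new)
      if (!is.null(gls_new)) {
        dev_new <- sweep_deviance(asm, G_new, R_new, gls_new$beta)
        if (!is.null(dev_new) && dev_new <= dev_cur + 1e-10) {
          G <- G_new; R <- R_new; gls <- gls_new
          ok <- TRUE
          break
        }
      }
      step <- step / 2
      halvings_total <- halvings_total + 1L
    }
    dev_old <- dev_cur
    if (!ok || iter >= control$max_iter) break
  }

  # final quantities at the accepted parameters
  si <- score_info(asm, G, R, gls$beta, gls$chols, U, rpar)
  deviance <- si$deviance
  info_free <- si$info[free_idx, free_idx, drop = FALSE]
  cov_free <- tryCatch(solve(info_free), error = function(e) MASS::ginv(info_free))
  nG_free <- sum(!constrained)
  gamma <- matrix(0, nrow(pairs), nrow(pairs), dimnames = list(pairs$name, pairs$name))
  gamma[!constrained, !constrained] <- cov_free[seq_len(nG_free), seq_len(nG_free)]
  gamma <- (gamma + t(gamma)) / 2
  gamma_all <- matrix(
    0, nrow(pairs) + nrow(rpar), nrow(pairs) + nrow(rpar),
    dimnames = list(c(pairs$name, rpar$name), c(pairs$name, rpar$name))
  )
  gamma_all[free_idx, free_idx] <- cov_free
  vcov_fixef <- tryCatch(solve(gls$XtPX), error = function(e) MASS::ginv(gls$XtPX))
  dimnames(vcov_fixef) <- list(asm$fe_names, asm$fe_names)

  if (!converged) {
    warn(sprintf(
      "scoring did not converge after %d iteration(s); returning best-so-far parameters (score norm %.3g).",
      iter, score_norm
    ))
  }

  structure(
    list(
      fixef = tibble::tibble(
        term = asm$fe_names,
        estimate = gls$beta,
        std.error = sqrt(pmax(diag(vcov_fixef), 0))
      ),
      G = G, R = R,
      deviance = deviance,
      logLik = -deviance / 2,
      gamma = gamma,
      gamma_all = gamma_all,
      vcov_fixef = vcov_fixef,
      ranef = spec$ranef,
      pairs = pairs,
      constraints = constraints,
      convergence = list(
        converged = converged, iterations = iter,
        score_norm = score_norm, step_halvings = halvings_total
      ),
      n_individuals = length(asm$ids),
      n_obs = asm$n_obs,
      fingerprint = asm$fingerprint,
      spec = spec,
      data = data
    ),
    class = "mlm_fit"
  )
}

constrained_mask <- function(pairs, terms, constraints) {
  if (is.null(constraints) || nrow(constraints) == 0L) {
    return(rep(FALSE, nrow(pairs)))
  }
  key <- paste(terms[pairs$a], terms[pairs$b], sep = "||")
  ckey <- paste(constraints$term_a, constraints$term_b, sep = "||")
  key %in% ckey
}

G_to_vech <- function(G, pairs) G[cbind(pairs$a, pairs$b)]

vech_to_G <- function(theta, pairs, M, terms) {
  G <- matrix(0, M, M, dimnames = list(terms, terms))
  G[cbind(pairs$a, pairs$b)] <- theta
  G[cbind(pairs$b, pairs$a)] <- theta
  G
}

zero_constrained <- function(G, pairs, constrained, terms) {
  theta <- G_to_vech(G, pairs)
  theta[constrained] <- 0
  vech_to_G(theta, pairs, nrow(G), terms)
}

default_start <- function(asm, spec, init) {
  responses <- asm$responses
  M <- asm$M
  # per-response OLS on the stacked design
  y <- unlist(purrr::map(asm$individuals, "y"), use.names = FALSE)
  X <- do.call(rbind, purrr::map(asm$individuals, "X"))
  resp <- unlist(purrr::map(asm$individuals, "resp"), use.names = FALSE)
  beta0 <- numeric(length(asm$fe_names))
  resid_var <- numeric(length(responses))
  for (r in seq_along(responses)) {
    rows <- resp == r
    cols <- startsWith(asm$fe_names, paste0(responses[r], ":"))
    f <- stats::lm.fit(X[rows, cols, drop = FALSE], y[rows])
    beta0[cols] <- f$coefficients
    resid_var[r] <- var(f$residuals)
  }
  beta0[is.na(beta0)] <- 0
  gdiag <- numeric(M)
  for (i in seq_len(M)) {
    r <- match(spec$ranef$response[i], responses)
    s <- spec$specs[[r]]
    span <- s$horizon - s$baseline
    gdiag[i] <- if (spec$ranef$kind[i] == "intercept") {
      resid_var[r]
    } else {
      resid_var[r] / span^2
    }
  }
  G0 <- diag(gdiag, M)
  dimnames(G0) <- list(spec$ranef$term, spec$ranef$term)
  R0 <- diag(resid_var / 2, length(responses))
  dimnames(R0) <- list(responses, responses)
  if (!is.null(init$G)) {
    G0 <- init$G
    dimnames(G0) <- list(spec$ranef$term, spec$ranef$term)
  }
  if (!is.null(init$R)) {
    R0 <- if (is.null(dim(init$R))) matrix(init$R, 1L, 1L) else init$R
    dimnames(R0) <- list(responses, responses)
  }
  if (!is.null(init$fixef)) beta0 <- align_fixef(init$fixef, asm$fe_names)
  list(beta = beta0, G = G0, R = R0, resid_var = resid_var)
}

# ---- methods ----------------------------------------------------------------

#' @export
print.mlm_fit <- function(x, ...) {
  cat(sprintf(
    "<mlm_fit> %d response(s), %d individuals, %d observations\n",
    nrow(x$R), x$n_individuals, x$n_obs
  ))
  cat(sprintf(
    "  deviance %.3f (%s, %d iterations)\n", x$deviance,
    if (x$convergence$converged) "converged" else "NOT converged",
    x$convergence$iterations
  ))
  if (!is.null(x$constraints) && nrow(x$constraints)) {
    cat(sprintf("  %d covariance(s) constrained to zero\n", nrow(x$constraints)))
  }
  cat("Fixed effects:\n")
  print(x$fixef, n = Inf)
  invisible(x)
}

#' Tidy a fitted multilevel spline model
#'
#' @param x An `mlm_fit`.
#' @param effects `"fixed"` for the fixed-effect table, `"ran_pars"` for the
#'   unique entries of `G` (with standard errors from `Gamma`) and the
#'   occasion-level parameters.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mlm_fit
#' @export
tidy.mlm_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    return(x$fixef)
  }
  pr <- x$pairs
  terms <- x$ranef$term
  est <- x$G[cbind(pr$a, pr$b)]
  se <- sqrt(pmax(diag(x$gamma), 0))
  gtab <- tibble::tibble(
    level = "individual",
    term_a = terms[pr$a], term_b = terms[pr$b],
    kind = ifelse(pr$a == pr$b, "variance", "covariance"),
    estimate = est, std.error = se,
    constrained = est == 0 & se == 0 &
      constrained_mask(pr, terms, x$constraints)
  )
  rpar <- rpar_index(rownames(x$R))
  rtab <- tibble::tibble(
    level = "occasion",
    term_a = rownames(x$R)[rpar$r1], term_b = rownames(x$R)[rpar$r2],
    kind = ifelse(rpar$type == "var", "variance", "covariance"),
    estimate = extract_R_theta(x$R, rpar),
    std.error = sqrt(pmax(diag(x$gamma_all)[nrow(pr) + seq_len(nrow(rpar))], 0)),
    constrained = FALSE
  )
  dplyr::bind_rows(gtab, rtab)
}

#' One-row model summary
#'
#' @param x An `mlm_fit`.
#' @param ... Unused.
#' @return A tibble with deviance, log-likelihood, counts and convergence.
#' @method glance mlm_fit
#' @export
glance.mlm_fit <- function(x, ...) {
  tibble::tibble(
    deviance = x$deviance,
    logLik = x$logLik,
    n_individuals = x$n_individuals,
    n_obs = x$n_obs,
    n_constraints = if (is.null(x$constraints)) 0L else nrow(x$constraints),
    iterations = x$convergence$iterations,
    converged = x$convergence$converged
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Likelihood-ratio test between nested covariance-constrained fits
#'
#' The restricted model must constrain a strict superset of the full model's
#' constrained covariances and be fitted to the same data. The statistic is
#' the deviance difference and the degrees of freedom the number of
#' additional constrained covariances. A negative statistic (possible only
#' through failed convergence) raises a warning and reports p = 1.
#'
#' @param full,restricted `mlm_fit` objects.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, and the two
#'   deviances.
#' @export
lrt <- function(full, restricted) {
  stopifnot(inherits(full, "mlm_fit"), inherits(restricted, "mlm_fit"))
  if (!isTRUE(all.equal(full$fingerprint, restricted$fingerprint))) {
    abort("models were fitted to different data; the LRT is not defined.")
  }
  if (!identical(full$ranef$term, restricted$ranef$term)) {
    abort("models have different random-effect structures.")
  }
  key <- function(cs) {
    if (is.null(cs)) character() else paste(cs$term_a, cs$term_b, sep = "||")
  }
  kf <- key(full$constraints)
  kr <- key(restricted$constraints)
  if (!all(kf %in% kr) || length(kr) <= length(kf)) {
    abort("`restricted` must constrain a strict superset of `full`'s covariances.")
  }
  lrt_from_deviance(full$deviance, restricted$deviance, length(kr) - length(kf))
}

#' Likelihood-ratio arithmetic from reported deviances
#'
#' @param deviance_full,deviance_restricted Deviances (-2 log-likelihood) of
#'   the nested fits.
#' @param df Number of covariances constrained in the restricted model beyond
#'   the full model.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, deviances.
#' @examples
#' lrt_from_deviance(984211.981, 984228.987, 4)  # p prints as 0.002
#' @export
lrt_from_deviance <- function(deviance_full, deviance_restricted, df) {
  stopifnot(df == as.integer(df), df >= 1)
  statistic <- deviance_restricted - deviance_full
  if (statistic < 0) {
    warn(paste(
      "negative likelihood-ratio statistic: one of the fits has not reached",
      "its maximum (numerical non-convergence); reporting p = 1."
    ))
    p <- 1
  } else {
    p <- pchisq(statistic, df = df, lower.tail = FALSE)
  }
  tibble::tibble(
    statistic = statistic, df = as.integer(df), p.value = p,
    deviance_full = deviance_full, deviance_restricted = deviance_restricted
  )
}

#' Empirical-Bayes (BLUP) predictions of individual random effects
#'
#' Returns the best linear unbiased predictions `G Z_k' V_k^{-1} e_k` of each
#' individual's random-effect vector. These are shrunken towards zero in
#' proportion to each individual's information, so their empirical covariance
#' understates `G`; use the model-estimated `G` (not the covariance of these
#' predictions) for population-level statements and for
#' [ranef_regression()].
#'
#' @param fit An `mlm_fit`.
#' @return A tibble with `id` and one column per random-effect term.
#' @export
ranef_blup <- function(fit) {
  stopifnot(inherits(fit, "mlm_fit"))
  asm <- assemble_individuals(fit$data, fit$spec)
  beta <- fit$fixef$estimate
  out <- matrix(0, length(asm$ids), asm$M,
    dimnames = list(NULL, fit$ranef$term)
  )
  for (i in seq_along(asm$individuals)) {
    ind <- asm$individuals[[i]]
    Vk <- ind$Z %*% fit$G %*% t(ind$Z) + build_Rk(ind, fit$R)
    e <- ind$y - drop(ind$X %*% beta)
    out[i, ] <- drop(fit$G %*% crossprod(ind$Z, solve(Vk, e)))
  }
  dplyr::bind_cols(tibble::tibble(id = asm$ids), tibble::as_tibble(out))
}

#' Marginal moments of one individual's stacked observation vector
#'
#' Model-implied mean and covariance for a given occasion schedule, useful
#' for moment checks and for the structural-equation comparison.
#'
#' @param fit An `mlm_fit`.
#' @param times Numeric vector of occasion times shared by every response.
#' @return A list with `mean`, `cov` and a `rows` tibble (response, time).
#' @export
mlm_marginal_moments <- function(fit, times) {
  spec <- fit$spec
  grid_data <- tidyr::expand_grid(
    response = names(spec$specs), time = as.numeric(times)
  )
  grid_data$id <- 1L
  grid_data$value <- 0
  for (cv in unique(unlist(spec$covariates))) grid_data[[cv]] <- 0
  asm <- assemble_individuals(grid_data, spec)
  ind <- asm$individuals[[1L]]
  V <- ind$Z %*% fit$G %*% t(ind$Z) + build_Rk(ind, fit$R)
  mu <- drop(ind$X %*% fit$fixef$estimate)
  list(
    mean = mu, cov = V,
    rows = tibble::tibble(
      response = asm$responses[ind$resp], time = ind$time
    )
  )
}

#' Staged fitting: add random effects one at a time
#'
#' Convergence for rich random-effect structures is easier when simpler
#' models are fitted first and their estimates reused as starting values.
#' This helper first fits each response univariately, then seeds the
#' multivariate fit with the univariate fixed effects, block-diagonal `G`
#' and occasion-level variances.
#'
#' @inheritParams fit_mlm
#' @return An `mlm_fit` for the full multivariate model.
#' @export
fit_mlm_staged <- function(data, spec, constraints = NULL,
                           control = mlm_control()) {
  if (!inherits(spec, "mlm_spec")) spec <- mlm_spec(spec)
  responses <- names(spec$specs)
  if (length(responses) == 1L) {
    return(fit_mlm(data, spec, constraints = constraints, control = control))
  }
  M <- nrow(spec$ranef)
  G0 <- matrix(0, M, M, dimnames = list(spec$ranef$term, spec$ranef$term))
  R0 <- matrix(0, length(responses), length(responses),
    dimnames = list(responses, responses)
  )
  fixef0 <- numeric(0)
  for (r in responses) {
    sub <- mlm_spec(spec$specs[r], covariates = spec$covariates[[r]])
    fr <- fit_mlm(data[data$response == r, , drop = FALSE], sub, control = control)
    cols <- which(spec$ranef$response == r)
    G0[cols, cols] <- fr$G
    R0[r, r] <- fr$R[1L, 1L]
    fixef0 <- c(fixef0, setNames(fr$fixef$estimate, fr$fixef$term))
  }
  fit_mlm(
    data, spec, constraints = constraints,
    init = list(fixef = fixef0, G = G0, R = R0), control = control
  )
}
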