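# Directed Bernoulli stochastic block model fitted by variational EM, with
# group count selected by the integrated complete-data likelihood (ICL).
#
# Model: nodes i = 1..n carry latent group labels z_i ~ Multinomial(alpha);
# conditional on labels, dyads (i != j) are independent Bernoulli with
# P(A_ij = 1 | z_i = q, z_j = r) = pi_qr. No self-loops. Edge types and
# weights are ignored during fitting: the model is fitted to the binary
# structure of the metaweb.

.EPS <- 1e-10

check_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (any(A != 0 & A != 1)) stop("adjacency must be binary")
  if (any(diag(A) != 0)) stop("self-loops are not allowed")
  storage.mode(A) <- "double"
  A
}

tau_from_labels <- function(z, Q, sharp = 0.95) {
  n <- length(z)
  tau <- matrix((1 - sharp) / max(Q - 1, 1), n, Q)
  tau[cbind(seq_len(n), z)] <- if (Q == 1) 1 else sharp
  tau / rowSums(tau)
}

#' Initialize variational responsibilities
#'
#' `"spectral"` runs k-means on the leading left singular vectors of the
#' concatenated out/in adjacency profiles `[A | t(A)]`, which separates groups
#' by their joint emission/reception pattern; `"random"` draws labels
#' uniformly. Both return softened one-hot rows (valid simplex rows).
#'
#' @param A binary adjacency matrix (no self-loops).
#' @param Q number of groups (1 <= Q <= n).
#' @param strategy `"spectral"` or `"random"`.
#' @param seed integer seed.
#' @return n x Q responsibility matrix, rows summing to 1.
#' @export
init_assignments <- function(A, Q, strategy = c("spectral", "random"),
                             seed = 1L) {
  A <- check_adjacency(A)
  strategy <- match.arg(strategy)
  n <- nrow(A)
  if (Q > n) stop("Q cannot exceed the number of nodes")
  if (Q == 1) return(matrix(1, n, 1))
  set.seed(seed)
  z <- if (strategy == "random") {
    sample.int(Q, n, replace = TRUE)
  } else {
    prof <- cbind(A, t(A))
    k <- min(Q, n - 1L)
    sv <- svd(prof, nu = k, nv = 0)
    emb <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
    km <- tryCatch(stats::kmeans(emb, centers = Q, nstart = 10, iter.max = 50),
                   error = function(e) NULL)
    if (is.null(km)) sample.int(Q, n, replace = TRUE) else km$cluster
  }
  # guarantee all Q columns have support
  missing <- setdiff(seq_len(Q), unique(z))
  if (length(missing) > 0) z[sample.int(n, length(missing))] <- missing
  tau_from_labels(z, Q)
}

sbm_mstep <- function(A, tau) {
  S <- colSums(tau)
  num <- crossprod(tau, A %*% tau)            # sum_{i!=j} tau_iq tau_jr A_ij
  den <- outer(S, S) - crossprod(tau)         # sum_{i!=j} tau_iq tau_jr
  pi <- num / pmax(den, .EPS)
  pi <- pmin(pmax(pi, 0), 1)
  list(alpha = S / nrow(tau), pi = pi, den = den, num = num)
}

sbm_elbo <- function(A, tau, alpha, pi) {
  m <- sbm_mstep(A, tau)
  lp <- log(pmin(pmax(pi, .EPS), 1 - .EPS))
  lq <- log(pmin(pmax(1 - pi, .EPS), 1 - .EPS))
  lik <- sum(m$num * lp + (m$den - m$num) * lq)
  mix <- sum(tau %*% log(pmax(alpha, .EPS)))
  ent <- -sum(tau * log(pmax(tau, .EPS)))
  lik + mix + ent
}

# one fixed-point sweep of the variational E-step
sbm_estep <- function(A, tau, alpha, pi) {
  n <- nrow(tau)
  lp <- log(pmin(pmax(pi, .EPS), 1 - .EPS))
  lq <- log(pmin(pmax(1 - pi, .EPS), 1 - .EPS))
  S <- colSums(tau)
  Mout <- A %*% tau                       # (i,r): sum_j A_ij tau_jr
  Min <- crossprod(A, tau)                # (i,r): sum_j A_ji tau_jr
  Nout <- matrix(S, n, length(S), byrow = TRUE) - tau - Mout
  Nin <- matrix(S, n, length(S), byrow = TRUE) - tau - Min
  L <- matrix(log(pmax(alpha, .EPS)), n, length(alpha), byrow = TRUE) +
    Mout %*% t(lp) + Nout %*% t(lq) +     # i as resource: pi_{q, r}
    Min %*% lp + Nin %*% lq               # i as consumer: pi_{r, q}
  L <- L - apply(L, 1, max)
  tau <- exp(L)
  tau / rowSums(tau)
}

.xlogy <- function(x, y) ifelse(x > 0, x * log(y), 0)

# complete-data log-likelihood from sufficient statistics: group sizes nq and
# group-pair edge counts E, MLE plug-in parameters (0 log 0 = 0)
loglik_from_counts <- function(nq, E, n) {
  N <- outer(nq, nq) - diag(nq, length(nq))
  phat <- ifelse(N > 0, E / N, 0)
  sum(.xlogy(nq, nq / n)) + sum(.xlogy(E, phat)) + sum(.xlogy(N - E, 1 - phat))
}

# greedy single-node label moves maximizing the complete-data log-likelihood;
# a classification-EM style polish of the hard assignment, implemented on the
# sufficient statistics so each candidate move costs O(Q^2)
refine_labels <- function(A, z, Q, max_sweeps = 20L) {
  n <- nrow(A)
  nq <- tabulate(z, Q)
  Z <- matrix(0, n, Q); Z[cbind(seq_len(n), z)] <- 1
  E <- crossprod(Z, A %*% Z)
  best <- loglik_from_counts(nq, E, n)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      a <- z[i]
      if (nq[a] == 1L) next  # never empty a group during refinement
      eout <- tabulate(z[A[i, ] == 1], Q)
      ein <- tabulate(z[A[, i] == 1], Q)
      for (b in seq_len(Q)) {
        if (b == a) next
        nq2 <- nq; nq2[a] <- nq2[a] - 1L; nq2[b] <- nq2[b] + 1L
        E2 <- E
        E2[a, ] <- E2[a, ] - eout; E2[b, ] <- E2[b, ] + eout
        E2[, a] <- E2[, a] - ein;  E2[, b] <- E2[, b] + ein
        ll <- loglik_from_counts(nq2, E2, n)
        if (ll > best + 1e-12) {
          z[i] <- b; nq <- nq2; E <- E2; best <- ll
          a <- b
          eout <- tabulate(z[A[i, ] == 1], Q)
          ein <- tabulate(z[A[, i] == 1], Q)
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(labels = z, loglik = best)
}

# complete-data log-likelihood at a hard assignment, with MLE plug-in
# parameters (0 log 0 = 0 convention)
complete_loglik <- function(A, z, Q = max(z)) {
  n <- nrow(A)
  Z <- matrix(0, n, Q); Z[cbind(seq_len(n), z)] <- 1
  nq <- colSums(Z)
  E <- crossprod(Z, A %*% Z)
  N <- outer(nq, nq) - crossprod(Z)   # dyads per group pair, no self-pairs
  phat <- ifelse(N > 0, E / N, 0)
  xlogy <- function(x, y) ifelse(x > 0, x * log(y), 0)
  sum(xlogy(nq, nq / n)) + sum(xlogy(E, phat)) + sum(xlogy(N - E, 1 - phat))
}

#' Fit a directed Bernoulli SBM by variational EM
#'
#' Alternates fixed-point updates of the responsibilities `tau` with
#' closed-form M-steps (`alpha_q = mean tau_.q`;
#' `pi_qr = sum tau_iq tau_jr A_ij / sum tau_iq tau_jr` over dyads `i != j`)
#' until the evidence lower bound (ELBO) changes by less than `tol` or
#' `max_iter` is reached. Groups whose responsibility mass collapses below
#' 1e-10 are merged away (Q is reduced and the fit flagged `degenerate`).
#' Hard labels are the argmax responsibilities polished by greedy single-node
#' moves on the complete-data log-likelihood (a classification-EM step that
#' stabilizes ICL scoring); the variational `tau`, `alpha`, `pi` are reported
#' as fitted.
#'
#' @param A binary adjacency, no self-loops.
#' @param Q requested group count.
#' @param tau0 initial responsibilities (defaults to spectral init).
#' @param tol ELBO convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param refine polish hard labels by greedy moves (default TRUE).
#' @return object of class `sbm_fit`: Q, tau, alpha, pi, labels, elbo_trace,
#'   elbo, loglik_complete, icl, degenerate flag.
#' @export
vem_fit <- function(A, Q, tau0 = NULL, tol = 1e-6, max_iter = 500L,
                    refine = TRUE) {
  A <- check_adjacency(A)
  n <- nrow(A)
  if (Q < 1 || Q > n) stop("Q must be in 1..n")
  tau <- if (is.null(tau0)) init_assignments(A, Q) else tau0
  if (ncol(tau) != Q || nrow(tau) != n) stop("tau0 has wrong dimensions")
  z_init <- max.col(tau, ties.method = "first")
  degenerate <- FALSE
  elbo_of <- function(tau) {
    m <- sbm_mstep(A, tau)
    sbm_elbo(A, tau, m$alpha, m$pi)
  }
  f_cur <- elbo_of(tau)
  trace <- f_cur
  for (it in seq_len(max_iter)) {
    m <- sbm_mstep(A, tau)
    tau_new <- sbm_estep(A, tau, m$alpha, m$pi)
    mass <- colSums(tau_new)
    if (any(mass < 1e-10) && ncol(tau_new) > 1) {
      keep <- mass >= 1e-10
      tau_new <- tau_new[, keep, drop = FALSE]
      tau_new <- tau_new / rowSums(tau_new)
      degenerate <- TRUE
      tau <- tau_new
      f_cur <- elbo_of(tau)
      trace <- f_cur   # Q changed: restart the trace for the reduced model
      next
    }
    f_new <- elbo_of(tau_new)
    if (f_new < f_cur - 1e-9) {
      # parallel fixed-point step overshot: damp towards the current tau
      accepted <- FALSE
      for (d in c(0.5, 0.25, 0.1)) {
        tau_d <- d * tau_new + (1 - d) * tau
        tau_d <- tau_d / rowSums(tau_d)
        f_d <- elbo_of(tau_d)
        if (f_d >= f_cur - 1e-12) {
          tau <- tau_d; f_new <- f_d; accepted <- TRUE; break
        }
      }
      if (!accepted) break  # no ascent direction left; keep current tau
    } else {
      tau <- tau_new
    }
    trace <- c(trace, f_new)
    if (f_new - f_cur < tol) { f_cur <- f_new; break }
    f_cur <- f_new
  }
  m <- sbm_mstep(A, tau)
  Qeff <- ncol(tau)
  z <- max.col(tau, ties.method = "first")
  if (refine && Qeff > 1) {
    # classification-EM polish from the converged responsibilities, and --
    # because VEM can funnel distinct inits into one attractor on small
    # graphs -- also from the initialization's hard labels; keep the better
    ref <- refine_labels(A, z, Qeff)
    z <- ref$labels
    llc <- ref$loglik
    if (Qeff == Q && length(unique(z_init)) == Qeff) {
      ref0 <- refine_labels(A, z_init, Qeff)
      if (ref0$loglik > llc + 1e-12) {
        z <- ref0$labels
        llc <- ref0$loglik
      }
    }
  } else llc <- complete_loglik(A, z, Qeff)
  fit <- structure(list(Q = Qeff, tau = tau, alpha = m$alpha, pi = m$pi,
                        labels = z, elbo_trace = trace,
                        elbo = trace[length(trace)],
                        loglik_complete = llc, n = n,
                        degenerate = degenerate),
                   class = "sbm_fit")
  fit$icl <- icl_score(fit, n)
  fit
}

# re-polish an existing fit's hard labels (used by select_Q so the greedy
# sweep runs once per Q, not once per restart)
refine_fit <- function(A, fit) {
  if (fit$Q > 1) {
    ref <- refine_labels(A, fit$labels, fit$Q)
    fit$labels <- ref$labels
    fit$loglik_complete <- ref$loglik
  }
  fit$icl <- icl_score(fit, fit$n)
  fit
}

#' @export
print.sbm_fit <- function(x, ...) {
  cat(sprintf("<sbm_fit> n=%d Q=%d ELBO=%.3f ICL=%.3f%s\n", x$n, x$Q, x$elbo,
              x$icl, if (x$degenerate) " (degenerate groups merged)" else ""))
  invisible(x)
}

#' Integrated complete-data likelihood of a fitted SBM
#'
#' `ICL = log L_c(hard labels; MLE params) - (Q^2 / 2) log(n (n - 1))
#'  - ((Q - 1) / 2) log n`, the BIC-style penalty for the Q^2 connection
#' probabilities (one observation per ordered dyad) and Q - 1 free mixing
#' proportions.
#'
#' @param fit an `sbm_fit`.
#' @param n number of nodes.
#' @return the ICL value (invariant under group relabelling).
#' @export
icl_score <- function(fit, n = fit$n) {
  Q <- fit$Q
  fit$loglik_complete - Q^2 / 2 * log(n * (n - 1)) - (Q - 1) / 2 * log(n)
}

#' Select the number of trophic groups by ICL
#'
#' Fits the SBM for every Q in `Q_range` with one spectral initialization and
#' `restarts - 1` random restarts, keeps the best ELBO fit per Q, and returns
#' the fit with maximal ICL (ties broken towards the smallest Q).
#'
#' @param A binary adjacency.
#' @param Q_range integer vector of candidate group counts.
#' @param restarts initializations per Q (>= 1).
#' @param seed integer seed controlling all initializations.
#' @param tol,max_iter passed to [vem_fit()].
#' @return the best `sbm_fit`, with `icl_table` (data.frame Q, elbo, icl)
#'   attached.
#' @export
select_Q <- function(A, Q_range = 1:25, restarts = 10L, seed = 1L,
                     tol = 1e-6, max_iter = 500L) {
  A <- check_adjacency(A)
  if (length(Q_range) == 0) stop("Q_range must be non-empty")
  Q_range <- sort(unique(as.integer(Q_range)))
  Q_range <- Q_range[Q_range >= 1 & Q_range <= nrow(A)]
  if (length(Q_range) == 0) stop("no feasible Q in Q_range")
  fits <- vector("list", length(Q_range))
  for (k in seq_along(Q_range)) {
    Q <- Q_range[k]
    best <- NULL
    for (r in seq_len(max(restarts, 1L))) {
      strat <- if (r == 1) "spectral" else "random"
      tau0 <- init_assignments(A, Q, strategy = strat,
                               seed = seed + 1000L * Q + r)
      f <- vem_fit(A, Q, tau0 = tau0, tol = tol, max_iter = max_iter,
                   refine = FALSE)
      if (is.null(best) || f$elbo > best$elbo) best <- f
    }
    fits[[k]] <- refine_fit(A, best)
  }
  icl <- vapply(fits, function(f) f$icl, 0)
  qeff <- vapply(fits, function(f) f$Q, 0L)
  # ties (within numerical fuzz) go to the smallest Q
  best_icl <- max(icl)
  winner <- which(icl >= best_icl - 1e-9)
  winner <- winner[which.min(qeff[winner])]
  out <- fits[[winner]]
  out$icl_table <- data.frame(Q_requested = Q_range, Q_effective = qeff,
                              elbo = vapply(fits, function(f) f$elbo, 0),
                              icl = icl)
  out
}

#' Derive the trophic-group metaweb from a fitted SBM
#'
#' Taxa are assigned to their hard group; the group-level graph has one node
#' per group and edge weights equal to the fitted connection probabilities
#' `pi` (including within-group "self" probabilities, reported in
#' `self_weight`). Each group is labelled by the majority guild of its
#' members when guilds are supplied.
#'
#' @param fit an `sbm_fit`.
#' @param node_ids optional node names (default `v1..vn`).
#' @param guild optional named guild vector for majority labelling.
#' @param threshold minimum pi for a group-pair edge to be materialized.
#' @return list of class `group_metaweb`: membership (named), web
#'   ([food_web()] over groups), pi, self_weight, group_guild.
#' @export
group_metaweb <- function(fit, node_ids = NULL, guild = NULL, threshold = 0) {
  stopifnot(inherits(fit, "sbm_fit"))
  if (is.null(node_ids)) node_ids <- sprintf("v%d", seq_len(fit$n))
  membership <- stats::setNames(fit$labels, node_ids)
  Q <- fit$Q
  gids <- sprintf("G%02d", seq_len(Q))
  pairs <- which(fit$pi > threshold, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  edges <- if (nrow(pairs) > 0)
    data.frame(resource = gids[pairs[, 1]], consumer = gids[pairs[, 2]],
               type = "predation",
               weight = fit$pi[pairs],
               stringsAsFactors = FALSE) else NULL
  group_guild <- rep(NA_character_, Q)
  if (!is.null(guild)) {
    for (q in seq_len(Q)) {
      g <- guild[node_ids[fit$labels == q]]
      g <- g[!is.na(g)]
      if (length(g) > 0)
        group_guild[q] <- names(sort(table(g), decreasing = TRUE))[1]
    }
  }
  web <- food_web(gids, edges, meta = list(level = "group"))
  structure(list(membership = membership, web = web, pi = fit$pi,
                 self_weight = diag(fit$pi),
                 group_guild = stats::setNames(group_guild, gids)),
            class = "group_metaweb")
}
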