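# Transposition-in-transposition (TinT): a younger element that inserted
# inside an older copy splits the older annotation into two fragments that
# share a repeat ID and are consensus-contiguous.  Each directed nesting
# (inner family i inside outer family j) certifies that i transposed after
# j did, and the collection of counts constrains the relative activity
# periods of all families on a pseudo-time axis.

#' Detect transposition-in-transposition events from annotation geometry
#'
#' Emits one event per inner entity found strictly between two consecutive
#' fragments of an outer entity, when the outer fragments (i) share a
#' repeat ID, (ii) are consensus-contiguous — the downstream fragment's
#' `rep_start` is at least the upstream fragment's `rep_end` minus
#' `tolerance` (RepeatMasker fragment endpoints jitter by a few dozen
#' consensus bases) — and (iii) leave at least one base of outer sequence on
#' each side of the inner entity.  An inner entity fragmented further (depth
#' two nesting) still counts once.
#'
#' @param copies Copy table from [read_rmsk_out()].
#' @param tolerance Consensus-continuity tolerance in consensus bases.
#' @return Data frame of events: `inner_entity`, `outer_entity`,
#'   `inner_family`, `outer_family`, `query_name`, `gap_start`, `gap_end`,
#'   and the flanking outer fragments' consensus coordinates
#'   (`outer_rep_end_left`, `outer_rep_start_right`).
#' @export
detect_tint_events <- function(copies, tolerance = 30) {
  ents <- group_entities(copies)
  empty <- data.frame(inner_entity = character(), outer_entity = character(),
                      inner_family = character(), outer_family = character(),
                      query_name = character(), gap_start = integer(),
                      gap_end = integer(), outer_rep_end_left = integer(),
                      outer_rep_start_right = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(ents) == 0L) return(empty)
  key <- entity_key(copies)
  multi <- ents$entity[ents$n_fragments >= 2L]
  events <- list()
  for (ek in multi) {
    fr <- copies[key == ek, , drop = FALSE]
    fr <- fr[order(fr$query_start), ]
    for (k in seq_len(nrow(fr) - 1L)) {
      gap_s <- fr$query_end[k]
      gap_e <- fr$query_start[k + 1L]
      if (gap_e <= gap_s) next
      # consensus continuity across the gap (consensus runs 3'->5' along the
      # genome for minus-strand entities)
      if (fr$strand[1] != "-") {
        if (fr$rep_start[k + 1L] < fr$rep_end[k] - tolerance) next
      } else {
        if (fr$rep_start[k] < fr$rep_end[k + 1L] - tolerance) next
      }
      inside <- ents$query_name == fr$query_name[1] &
        ents$entity != ek &
        ents$span_start >= gap_s & ents$span_end <= gap_e
      if (!any(inside)) next
      inner <- ents[inside, , drop = FALSE]
      outer_fam <- ents$family[ents$entity == ek]
      events[[length(events) + 1L]] <- data.frame(
        inner_entity = inner$entity, outer_entity = ek,
        inner_family = inner$family, outer_family = outer_fam,
        query_name = fr$query_name[1],
        gap_start = gap_s, gap_end = gap_e,
        outer_rep_end_left = fr$rep_end[k],
        outer_rep_start_right = fr$rep_start[k + 1L],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Aggregate TinT events into a directed nesting-count matrix
#'
#' @param events Data frame from [detect_tint_events()].
#' @param family_list Families to keep (row/column order); events involving
#'   other families are ignored.
#' @return Integer matrix `N` with `N[i, j]` = events with inner family `i`
#'   inside outer family `j`.
#' @export
build_nesting_matrix <- function(events, family_list) {
  keep <- events$inner_family %in% family_list &
    events$outer_family %in% family_list
  tab <- table(factor(events$inner_family[keep], levels = family_list),
               factor(events$outer_family[keep], levels = family_list))
  m <- matrix(as.integer(tab), nrow = length(family_list),
              dimnames = list(inner = family_list, outer = family_list))
  m
}

# model internals -------------------------------------------------------------

# q_{ij} = c_j * Phi((mu_i - mu_j)/sqrt(s_i^2 + s_j^2)): the propensity for
# family i to land inside family j, the product of target abundance and the
# probability that a random i-insertion postdates a random j-insertion when
# both activity profiles are Normal.
.tint_q <- function(mu, sigma, cw) {
  k <- length(mu)
  den <- sqrt(outer(sigma^2, sigma^2, "+"))
  q <- matrix(rep(cw, each = k), k, k) * stats::pnorm(outer(mu, mu, "-") / den)
  q
}

# row-normalized over targets; self-nesting (i = j) stays in the model with
# the parameter-free precedence probability Phi(0) = 1/2 -- a family that
# nests only within itself thereby testifies that every other family
# postdates it, which is what orders the oldest member
.tint_p <- function(mu, sigma, cw) {
  q <- .tint_q(mu, sigma, cw)
  q / pmax(rowSums(q), .Machine$double.xmin)
}

.tint_loglik <- function(mu, sigma, cw, N) {
  p <- .tint_p(mu, sigma, cw)
  sum(N * log(pmax(p, 1e-300)))
}

#' Infer relative family activity periods from nesting counts
#'
#' Fits a two-parameter-per-family activity model on pseudo-time by maximum
#' likelihood.  Family `f`'s activity is `Normal(mu_f, sigma_f^2)`;
#' conditional on an event with inner family `i`, the outer family is
#' multinomial over targets `j != i` with probabilities proportional to
#' `c_j * Phi((mu_i - mu_j) / sqrt(sigma_i^2 + sigma_j^2))` — target
#' abundance `c_j` times the probability that the inner copy postdates the
#' outer one.  Pseudo-time increases toward the present, so larger `mu`
#' means younger.  Self-nesting events keep the parameter-free precedence
#' probability `Phi(0) = 1/2`; they carry no direct ordering signal of
#' their own but compete in each row's normalization, so a family observed
#' nesting only within itself is correctly inferred to predate the
#' families it avoided.  The scale and origin are fixed by anchoring the
#' first family's `mu` at 0 and the geometric mean of the `sigma` at 1.
#' Optimization is multi-start L-BFGS-B (one start from a net-precedence
#' rank heuristic, the rest random), deterministic given `seed`.  Families
#' with no event in either direction are reported as `unconstrained` with
#' the widest interval rather than silently placed.
#'
#' @param N Nesting matrix from [build_nesting_matrix()].
#' @param copy_weights Target-abundance weights `c_j` (entity counts or
#'   annotated-base totals per family), in `colnames(N)` order; defaults to
#'   equal weights.
#' @param restarts Number of random optimizer starts.
#' @param seed Integer seed for the starts.
#' @return Data frame with one row per family: `family`, `mu`, `sigma`,
#'   interval bounds `lo75/hi75`, `lo95/hi95`, `lo99/hi99` (central
#'   quantiles of `Normal(mu, sigma^2)`), `unconstrained` flag, plus
#'   attributes `loglik` and `p_matrix`.
#' @export
infer_activity_periods <- function(N, copy_weights = NULL, restarts = 20,
                                   seed = 1) {
  fams <- rownames(N)
  k <- length(fams)
  if (k < 2L) stop("need at least 2 families")
  off <- N
  diag(off) <- 0L
  if (sum(off) < 1L) stop("no off-diagonal nesting counts")
  constrained <- (rowSums(N) + colSums(N)) > 0
  fit_f <- fams[constrained]
  m <- length(fit_f)
  Nf <- N[fit_f, fit_f, drop = FALSE]
  cw <- if (is.null(copy_weights)) rep(1, k) else {
    stopifnot(length(copy_weights) == k, all(copy_weights > 0))
    copy_weights
  }
  names(cw) <- fams
  cwf <- cw[fit_f]

  # theta = (mu_2..mu_m, log sigma_1..log sigma_{m-1});
  # mu_1 = 0, sum(log sigma) = 0
  unpack <- function(theta) {
    mu <- c(0, theta[seq_len(m - 1)])
    ls <- theta[m - 1 + seq_len(m - 1)]
    ls <- c(ls, -sum(ls))
    list(mu = mu, sigma = exp(ls))
  }
  nll <- function(theta) {
    par <- unpack(theta)
    -.tint_loglik(par$mu, par$sigma, cwf, Nf)
  }
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  # net-precedence heuristic start: families that act as inner more than as
  # outer are ranked younger
  net <- rowSums(Nf) - diag(Nf) - (colSums(Nf) - diag(Nf))
  mu_h <- (rank(net, ties.method = "first") - (m + 1) / 2) * (4 / m)
  mu_h <- mu_h - mu_h[1]
  best <- NULL
  for (r in seq_len(restarts)) {
    th0 <- if (r == 1L) c(mu_h[-1], rep(0, m - 1))
           else c(stats::rnorm(m - 1, 0, 2), stats::rnorm(m - 1, 0, 0.3))
    fit <- tryCatch(
      stats::optim(th0, nll, method = "L-BFGS-B",
                   lower = c(rep(-30, m - 1), rep(-4, m - 1)),
                   upper = c(rep(30, m - 1), rep(4, m - 1)),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("optimization failed for all restarts")
  par <- unpack(best$par)
  mu <- stats::setNames(rep(NA_real_, k), fams)
  sg <- mu
  mu[fit_f] <- par$mu
  sg[fit_f] <- par$sigma
  # unconstrained families: flagged, centered with a deliberately wide width
  if (any(!constrained)) {
    mu[!constrained] <- mean(par$mu)
    sg[!constrained] <- 4 * max(par$sigma)
  }
  zz <- stats::qnorm(c(0.875, 0.975, 0.995))
  res <- data.frame(
    family = fams, mu = unname(mu), sigma = unname(sg),
    lo75 = unname(mu - zz[1] * sg), hi75 = unname(mu + zz[1] * sg),
    lo95 = unname(mu - zz[2] * sg), hi95 = unname(mu + zz[2] * sg),
    lo99 = unname(mu - zz[3] * sg), hi99 = unname(mu + zz[3] * sg),
    unconstrained = !constrained,
    stringsAsFactors = FALSE)
  attr(res, "loglik") <- -best$value
  attr(res, "p_matrix") <- .tint_p(par$mu, par$sigma, cwf)
  res
}

#' Report the one-sided nesting partners of the youngest family
#'
#' For the family with maximal inferred `mu`, lists the partner families
#' into which it nests (positive inner count) without ever hosting them
#' (zero outer count) — the signature of the terminal member of a
#' succession.
#'
#' @param periods Result of [infer_activity_periods()].
#' @param N The nesting matrix the periods were fitted to.
#' @return Data frame `partner`, `n_inner` (youngest inside partner),
#'   `n_outer` (partner inside youngest), `one_sided`; zero rows when the
#'   matrix is empty or no family passes.
#' @export
youngest_family_check <- function(periods, N) {
  empty <- data.frame(partner = character(), n_inner = integer(),
                      n_outer = integer(), one_sided = logical(),
                      stringsAsFactors = FALSE)
  off <- N
  diag(off) <- 0L
  if (sum(off) == 0L) return(empty)
  ok <- periods[!periods$unconstrained, ]
  y <- ok$family[which.max(ok$mu)]
  partners <- setdiff(rownames(N), y)
  res <- data.frame(partner = partners,
                    n_inner = as.integer(N[y, partners]),
                    n_outer = as.integer(N[partners, y]),
                    stringsAsFactors = FALSE)
  res$one_sided <- res$n_inner > 0L & res$n_outer == 0L
  res <- res[res$n_inner > 0L | res$n_outer > 0L, , drop = FALSE]
  attr(res, "youngest") <- y
  rownames(res) <- NULL
  res
}

#' Sample nesting counts from the activity model itself
#'
#' The model's own generative form, used for parameter-recovery checks:
#' draws `n_events` inner families uniformly, then outer targets from the
#' model's conditional multinomial.
#'
#' @param mu,sigma Per-family parameters (named vectors, same order).
#' @param copy_weights Target abundances `c_j`.
#' @param n_events Number of events to draw.
#' @param seed Integer seed.
#' @return Integer nesting matrix.
#' @export
simulate_nesting_counts <- function(mu, sigma, copy_weights = NULL,
                                    n_events = 2000, seed = 1) {
  k <- length(mu)
  fams <- names(mu)
  if (is.null(fams)) fams <- paste0("fam", seq_len(k))
  if (is.null(copy_weights)) copy_weights <- rep(1, k)
  p <- .tint_p(mu, sigma, copy_weights)
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  N <- matrix(0L, k, k, dimnames = list(inner = fams, outer = fams))
  inner <- sample.int(k, n_events, replace = TRUE)
  for (i in seq_len(k)) {
    ni <- sum(inner == i)
    if (ni == 0L) next
    draws <- stats::rmultinom(1, ni, p[i, ])
    N[i, ] <- N[i, ] + as.integer(draws)
  }
  N
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
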