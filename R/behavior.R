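# Mount-event scoring and the nonparametric group tests (Mann-Whitney U
# with exact enumeration, Kruskal-Wallis with tie correction).  The test
# statistics are authored here rather than wrapped so that exact
# enumeration, tie handling and continuity correction are explicit and
# testable.

#' Score mounting behavior per animal
#'
#' @param table event data.frame (`animal_id`, `group`, `event_start_s`,
#'   `event_end_s`), e.g. from [generate_behavior_table()] or
#'   [read_behavior_csv()].  Animals with no events are taken from the
#'   `animals` attribute (roster) when present.
#' @param session_length_s session length; animals that never mount get
#'   this value as their latency sentinel.  Taken from the roster when
#'   `NULL`.
#' @return data.frame per animal: `animal_id`, `group`, `n_mounts`,
#'   `total_duration_s`, `latency_s`.
#' @export
score_mounting <- function(table, session_length_s = NULL) {
  roster <- attr(table, "animals")
  if (is.null(roster)) {
    if (is.null(session_length_s))
      stop("session_length_s required when the table has no roster")
    roster <- unique(data.frame(animal_id = table$animal_id,
                                group = table$group,
                                session_length_s = session_length_s))
  }
  if (nrow(table) > 0) {
    bad <- table$event_start_s < 0 | table$event_end_s <= table$event_start_s
    if (any(bad)) stop("invalid event interval(s)")
    for (id in unique(table$animal_id)) {
      ev <- table[table$animal_id == id, ]
      ev <- ev[order(ev$event_start_s), ]
      if (nrow(ev) > 1L &&
          any(ev$event_start_s[-1L] < ev$event_end_s[-nrow(ev)]))
        stop("overlapping events for animal ", id)
    }
  }
  out <- lapply(seq_len(nrow(roster)), function(i) {
    id <- roster$animal_id[i]
    sl <- roster$session_length_s[i]
    ev <- table[table$animal_id == id, , drop = FALSE]
    if (nrow(ev) > 0 && any(ev$event_end_s > sl + 1e-9))
      stop("event past session end for animal ", id)
    data.frame(animal_id = id, group = roster$group[i],
               n_mounts = nrow(ev),
               total_duration_s = sum(ev$event_end_s - ev$event_start_s),
               latency_s = if (nrow(ev)) min(ev$event_start_s) else sl)
  })
  do.call(rbind, out)
}

#' Mann-Whitney U test
#'
#' U is computed from midrank sums (`U = R_x - n_x(n_x+1)/2`).  The
#' two-sided p-value is exact by full enumeration of all
#' `choose(n_x+n_y, n_x)` group labelings when the combined sample size is
#' at most 12 and there are no ties (`method = "auto"`); otherwise a
#' normal approximation with tie correction and a 0.5 continuity
#' correction is used.  `method = "exact"` forces enumeration (a
#' permutation test over the observed midranks when ties are present).
#'
#' @param x,y non-empty numeric samples.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return list `U`, `p_value`, `method` (the method actually used).
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- switch(method,
                      exact = TRUE,
                      normal = FALSE,
                      auto = N <= 12L && !ties)
  if (use_exact) {
    mu <- nx * ny / 2
    combs <- utils::combn(N, nx)
    rs <- colSums(matrix(r[combs], nrow = nx))
    Us <- rs - nx * (nx + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    used <- if (ties) "exact (permutation over midranks)" else "exact"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- nx * ny / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    p <- min(p, 1)
    used <- "normal"
  }
  list(U = U, p_value = p, method = used)
}

#' Kruskal-Wallis test
#'
#' H from pooled midranks with tie correction; p from the chi-squared
#' distribution with k-1 degrees of freedom, or from a seeded permutation
#' null (`p_method = "permutation"`).
#'
#' @param groups list of at least 2 non-empty numeric samples.
#' @param p_method `"chisq"` or `"permutation"`.
#' @param n_perm permutation count.
#' @param perm_seed RNG seed for the permutation null.
#' @return list `H`, `df`, `p_value`, `p_method`.
#' @export
kruskal_wallis <- function(groups, p_method = c("chisq", "permutation"),
                           n_perm = 10000L, perm_seed = 1L) {
  p_method <- match.arg(p_method)
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(lengths(groups) == 0L)) stop("empty group")
  pooled <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  H <- kw_statistic(pooled, g)
  df <- length(groups) - 1L
  if (p_method == "chisq") {
    p <- stats::pchisq(H, df, lower.tail = FALSE)
  } else {
    set.seed(perm_seed)
    ge <- 0L
    for (b in seq_len(n_perm))
      if (kw_statistic(pooled, sample(g)) >= H - 1e-12) ge <- ge + 1L
    p <- (ge + 1) / (n_perm + 1)
  }
  list(H = H, df = df, p_value = p, p_method = p_method)
}

kw_statistic <- function(pooled, g) {
  N <- length(pooled)
  r <- rank(pooled)
  Rj <- tapply(r, g, sum)
  nj <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  tie_tab <- table(pooled)
  C <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (C > 0) H <- H / C
  H
}

#' Write / read behavior event tables as CSV
#'
#' CSV columns: `animal_id`, `group`, `event_start_s`, `event_end_s`.  The
#' roster (all animals, including those with no events) travels in a
#' companion `<path>.animals.csv` so zero-mount animals survive the round
#' trip.
#'
#' @param table a behavior event table (see [generate_behavior_table()]).
#' @param path file path.
#' @return `read_behavior_csv` returns the event table with its roster
#'   attribute.
#' @export
write_behavior_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  roster <- attr(table, "animals")
  if (!is.null(roster))
    utils::write.csv(roster, paste0(path, ".animals.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  rpath <- paste0(path, ".animals.csv")
  if (file.exists(rpath))
    attr(out, "animals") <- utils::read.csv(rpath, stringsAsFactors = FALSE)
  out
}

#' Group-difference report for mount summaries
#'
#' Runs Kruskal-Wallis across all groups and pairwise Mann-Whitney tests
#' for each scored endpoint (count, total duration, latency).
#'
#' @param summaries output of [score_mounting()].
#' @return Nested list by endpoint: `kruskal` and `pairwise` (data.frame
#'   of group pairs with U and p).
#' @export
behavior_report <- function(summaries) {
  endpoints <- c(n_mounts = "n_mounts", total_duration_s = "total_duration_s",
                 latency_s = "latency_s")
  grp <- split(summaries, summaries$group)
  lapply(endpoints, function(col) {
    samples <- lapply(grp, `[[`, col)
    kw <- kruskal_wallis(samples)
    pairs <- utils::combn(names(samples), 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      mw <- mann_whitney(samples[[pairs[1, j]]], samples[[pairs[2, j]]])
      data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                 U = mw$U, p_value = mw$p_value, method = mw$method)
    }))
    list(kruskal = kw, pairwise = pw)
  })
}
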