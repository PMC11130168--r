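#' Impute a missing overall tumour stage from N and M
#'
#' When the overall stage is recorded it is returned unchanged. When it is
#' missing, a patient with nodal involvement but no distant metastasis
#' (`N > 0` and `M == 0`) is classified as stage 3; otherwise the stage
#' stays missing. This is the standard rescue rule for clinical tables in
#' which only the TNM components were deposited.
#'
#' @param stage overall stage (numeric, NA when missing); vectorised.
#' @param N,M nodal / metastasis components (NA allowed).
#' @return the stage vector with the rule applied.
#' @examples
#' imputeStage(c(2, NA, NA), N = c(0, 1, 0), M = c(0, 0, 0))  # 2, 3, NA
#' @export
imputeStage <- function(stage, N, M) {
    n <- max(length(stage), length(N), length(M))
    stage <- rep_len(stage, n); N <- rep_len(N, n); M <- rep_len(M, n)
    fill <- is.na(stage) & !is.na(N) & !is.na(M) & N > 0 & M == 0
    stage[fill] <- 3
    stage
}

.checkSurvival <- function(time, event) {
    if (!length(time)) stop("at least one record is required")
    if (any(!is.finite(time)) || any(time <= 0))
        stop("survival times must be finite and positive")
    if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1")
    invisible(NULL)
}

#' Kaplan-Meier product-limit estimate
#'
#' \deqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over the distinct
#' event times, with d the number of events and n the number at risk.
#' Subjects censored at an event time are still at risk at that time
#' (events are processed before censorings at tied times).
#'
#' @param time follow-up in months (> 0).
#' @param event 1 = event, 0 = censored.
#' @return data.frame over distinct event times: `time`, `nRisk`, `nEvent`,
#'   `survival`; an attribute `"medianSurvival"` carries the smallest event
#'   time with survival <= 0.5 (NA if never reached).
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 1, 1))
#' @export
kmEstimate <- function(time, event) {
    .checkSurvival(time, event)
    eventTimes <- sort(unique(time[event == 1]))
    surv <- numeric(length(eventTimes))
    nRisk <- integer(length(eventTimes))
    nEvent <- integer(length(eventTimes))
    s <- 1
    for (j in seq_along(eventTimes)) {
        t0 <- eventTimes[j]
        nRisk[j] <- sum(time >= t0)
        nEvent[j] <- sum(time == t0 & event == 1)
        s <- s * (1 - nEvent[j] / nRisk[j])
        surv[j] <- s
    }
    out <- data.frame(time = eventTimes, nRisk = nRisk, nEvent = nEvent,
                      survival = surv)
    med <- if (any(surv <= 0.5)) eventTimes[which(surv <= 0.5)[1]] else NA_real_
    attr(out, "medianSurvival") <- med
    out
}

#' Log-rank test between survival curves
#'
#' At every distinct event time the observed events per group are compared
#' with the expectation under the hypergeometric null of exchangeable
#' groups; the statistic is \eqn{(O - E)^\top V^{-1} (O - E)} over the first
#' k - 1 groups and is referred to a chi-square distribution with k - 1
#' degrees of freedom.
#'
#' @param time follow-up in months (> 0).
#' @param event 1 = event, 0 = censored.
#' @param group group label per subject (>= 2 non-empty groups; at least one
#'   event overall).
#' @return list with `statistic`, `df`, `p.value`, and the per-group
#'   observed/expected table `table`.
#' @export
logrankTest <- function(time, event, group) {
    .checkSurvival(time, event)
    group <- factor(group)
    if (any(table(group) == 0) || nlevels(group) < 2)
        stop("at least two non-empty groups are required")
    if (sum(event) < 1) stop("at least one event is required")
    k <- nlevels(group)
    eventTimes <- sort(unique(time[event == 1]))

    O <- numeric(k); E <- numeric(k)
    V <- matrix(0, k, k)
    for (t0 in eventTimes) {
        atRisk <- time >= t0
        n <- sum(atRisk)
        d <- sum(time == t0 & event == 1)
        ng <- vapply(levels(group), function(g) sum(atRisk & group == g),
                     numeric(1))
        dg <- vapply(levels(group), function(g)
            sum(time == t0 & event == 1 & group == g), numeric(1))
        O <- O + dg
        E <- E + d * ng / n
        if (n > 1) {
            c0 <- d * (n - d) / (n - 1)
            V <- V + c0 * (diag(ng * n, k) - outer(ng, ng)) / n^2
        }
    }
    idx <- seq_len(k - 1)
    oe <- (O - E)[idx]
    Vi <- V[idx, idx, drop = FALSE]
    stat <- as.numeric(t(oe) %*% solve(Vi, oe))
    list(statistic = stat, df = k - 1,
         p.value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
         table = data.frame(group = levels(group), n = as.integer(table(group)),
                            observed = O, expected = E))
}

#' Tabulate subtype transitions in matched pre/post pairs
#'
#' Counts, for every pre-treatment subtype i and post-treatment subtype j,
#' the number of pairs moving from i to j, and reports the fraction of
#' pairs landing in each post-treatment subtype — the quantity behind
#' Sankey representations of therapy-induced subtype shifts.
#'
#' @param preLabels named vector: subtype of each pre sample, names =
#'   pair keys (or a vector aligned with `pairs`).
#' @param postLabels same for post samples.
#' @param pairs optional character vector of pair keys; defaults to the
#'   intersection of the names of the two label vectors. Every key must
#'   map to exactly one pre and one post sample.
#' @param classes optional label universe fixing row/column order.
#' @return a [TransitionTable-class].
#' @export
subtypeShiftTable <- function(preLabels, postLabels, pairs = NULL,
                              classes = NULL) {
    if (is.null(pairs)) {
        if (is.null(names(preLabels)) || is.null(names(postLabels)))
            stop("either name the label vectors by pair key or give 'pairs'")
        pairs <- union(names(preLabels), names(postLabels))
    }
    pre <- preLabels[pairs]
    post <- postLabels[pairs]
    bad <- pairs[is.na(pre) | is.na(post)]
    if (length(bad))
        stop("unpaired sample(s): ", paste(bad, collapse = ", "))
    if (is.null(classes)) classes <- sort(unique(c(pre, post)))
    counts <- table(factor(pre, levels = classes),
                    factor(post, levels = classes))
    counts <- matrix(as.integer(counts), nrow = length(classes),
                     dimnames = list(pre = classes, post = classes))
    frac <- if (sum(counts) > 0) colSums(counts) / sum(counts)
            else structure(rep(0, length(classes)), names = classes)
    new("TransitionTable", counts = counts, postFractions = frac)
}
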