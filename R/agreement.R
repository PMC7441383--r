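#' Krippendorff's alpha for nominal data
#'
#' Chance-corrected agreement between two or more raters on nominal labels,
#' computed with the coincidence-matrix formulation:
#' \eqn{\alpha = 1 - D_o / D_e}, where each unit with \eqn{m_u \ge 2} labels
#' contributes each ordered label pair with weight \eqn{1/(m_u - 1)} to the
#' coincidence matrix. Missing labels (raters who skipped a unit) are
#' allowed; units with fewer than two labels carry no information and are
#' ignored. Equivalent closed form used here:
#' \eqn{\alpha = 1 - (n-1)\sum_{c<k} o_{ck} / \sum_{c<k} n_c n_k}.
#'
#' @param x either a matrix/data.frame of labels with one row per unit and
#'   one column per rater (NA = missing), or a long-format data.frame with
#'   columns \code{item}, \code{rater}, \code{label}.
#' @return alpha, a single number \eqn{\le 1} (1 = perfect agreement, 0 =
#'   chance level, negative = systematic disagreement).
#' @examples
#' krippendorffAlpha(cbind(r1 = c("A", "A", "B", "A"),
#'                         r2 = c("A", "A", "B", "B")))
#' @export
krippendorffAlpha <- function(x) {
    if (is.data.frame(x) && all(c("item", "rater", "label") %in% names(x))) {
        dup <- stats::xtabs(~ item + rater, data = x)
        if (any(dup > 1L))
            stop("more than one label per (item, rater)")
        x <- .longToWide(x)
    }
    m <- as.matrix(x)
    labs <- sort(unique(stats::na.omit(as.vector(m))))
    L <- length(labs)
    o <- matrix(0, L, L, dimnames = list(labs, labs))
    for (u in seq_len(nrow(m))) {
        vals <- stats::na.omit(m[u, ])
        mu <- length(vals)
        if (mu < 2L) next
        idx <- match(vals, labs)
        for (a in seq_len(mu)) for (b in seq_len(mu)) if (a != b)
            o[idx[a], idx[b]] <- o[idx[a], idx[b]] + 1 / (mu - 1)
    }
    n <- sum(o)
    if (n == 0)
        stop("agreement undefined: no unit has two or more labels")
    nc <- rowSums(o)
    offDiag <- sum(o) - sum(diag(o))
    expDiag <- sum(outer(nc, nc)) - sum(nc^2)
    if (expDiag == 0) return(1)  # a single category observed
    1 - (n - 1) * offDiag / expDiag
}

.longToWide <- function(df) {
    wide <- stats::reshape(
        df[c("item", "rater", "label")], idvar = "item",
        timevar = "rater", direction = "wide")
    as.matrix(wide[, -1, drop = FALSE])
}

#' Cohen's kappa for two observers
#'
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with expected agreement from the
#' product of marginals. Can legitimately be near zero or negative even at
#' high raw agreement when the marginals are extremely skewed (the kappa
#' paradox); in the degenerate case \eqn{p_e = 1} kappa is undefined and an
#' error reporting the raw agreement is thrown.
#'
#' @param r1,r2 equal-length vectors of verdicts, one element per judged
#'   unit (same unit order in both).
#' @return kappa in \[-1, 1\].
#' @examples
#' cohenKappa(rep(c("a", "b"), c(25, 25)),
#'            rep(c("a", "b", "a", "b"), c(20, 5, 10, 15)))
#' @export
cohenKappa <- function(r1, r2) {
    if (length(r1) != length(r2))
        stop("observers judged different numbers of units")
    if (!length(r1)) stop("no judgments")
    labs <- sort(unique(c(as.character(r1), as.character(r2))))
    t1 <- factor(r1, levels = labs); t2 <- factor(r2, levels = labs)
    tab <- table(t1, t2)
    n <- sum(tab)
    po <- sum(diag(tab)) / n
    pe <- sum(rowSums(tab) * colSums(tab)) / n^2
    if (pe == 1)
        stop(sprintf(
            "kappa undefined (expected agreement is 1); raw agreement = %.4f",
            po))
    (po - pe) / (1 - pe)
}
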