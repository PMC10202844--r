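#' Build the longitudinal group-by-time model matrix
#'
#' Encodes the design used throughout the differential-expression stage:
#' seven columns in fixed order --- intercept, sex (F = 0, M = 1), centred
#' time `t`, `t^2`, group (CON = 0, MNR = 1), `group:t`, `group:t2`.
#' Gestational day is centred and scaled to `t = (dG - 127.5) / 37.5`, which
#' maps the sampled days 90/120/140/165 into `[-1, 1]`; raw day and
#' day-squared are nearly collinear over that range, and contrasts on the
#' interaction terms are invariant to this affine re-encoding when combined
#' with the remaining model terms.
#'
#' @param design data.frame with columns `group`, `sex`, `gestational_day`
#'   (as returned by [studyDesign()]), or a [TranscriptExperiment-class].
#' @param center,scale centre and scale of the time encoding.
#' @return numeric matrix, samples x 7, full column rank; an error naming
#'   the collinear columns is raised otherwise.
#' @examples
#' buildModelMatrix(paperDesign())
#' @export
buildModelMatrix <- function(design, center = 127.5, scale = 37.5) {
    if (is(design, "TranscriptExperiment")) design <- studyDesign(design)
    stopifnot(all(c("group", "sex", "gestational_day") %in% names(design)))
    if (!all(design$group %in% c("CON", "MNR")))
        stop("unknown group level (expected CON/MNR)")
    if (!all(design$sex %in% c("F", "M")))
        stop("unknown sex level (expected F/M)")
    t <- (design$gestational_day - center) / scale
    grp <- as.numeric(design$group == "MNR")
    X <- cbind(intercept = 1,
               sexM = as.numeric(design$sex == "M"),
               t = t,
               t2 = t^2,
               MNR = grp,
               MNR.t = grp * t,
               MNR.t2 = grp * t^2)
    if (!is.null(design$sample_id)) rownames(X) <- design$sample_id
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        dropped <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
        stop("model matrix is rank deficient; collinear columns: ",
             paste(dropped, collapse = ", "))
    }
    X
}

#' The reference longitudinal study design
#'
#' A 28-sample two-group design over gestational days 90, 120, 140 and 165:
#' eight CON and eight MNR samples at 90 and 165 dG, six and six at 120 and
#' 140 dG, with equal numbers of males and females in every group at every
#' timepoint.
#'
#' @return data.frame with columns `sample_id`, `group`, `sex`,
#'   `gestational_day`.
#' @examples
#' table(paperDesign()$group, paperDesign()$gestational_day)
#' @export
paperDesign <- function() {
    days <- c(90, 120, 140, 165)
    per <- c(`90` = 8, `120` = 6, `140` = 6, `165` = 8)
    rows <- do.call(rbind, lapply(days, function(d) {
        n <- per[[as.character(d)]]
        expand.grid(group = c("CON", "MNR"),
                    sex = rep(c("F", "M"), each = n / 2),
                    gestational_day = d,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    }))
    rows <- rows[order(rows$gestational_day, rows$group, rows$sex), ]
    rows$sample_id <- sprintf("s%02d", seq_len(nrow(rows)))
    rownames(rows) <- NULL
    rows[, c("sample_id", "group", "sex", "gestational_day")]
}
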