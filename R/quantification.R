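# Multi-mapping-corrected miRNA quantification: RPM = C/(M*N) * 1e9, where C
# is the read count aligned to a miRNA's region, M its multi-mapping
# multiplicity across all miRNA regions, and N the library's total
# genome-mapped read count. The 1e9 scale is applied exactly as defined, with
# no silent correction.

#' RPM value for one miRNA
#'
#' @param C read count aligned to the miRNA region (0 <= C <= N).
#' @param M multi-mapping multiplicity (>= 1).
#' @param N total genome-mapped reads in the library (>= 1).
#' @return `C / (M * N) * 1e9`; 0 when C is 0.
#' @export
rpm <- function(C, M, N) {
  if (any(M < 1) || any(N < 1)) stop("domain error: M and N must be >= 1")
  if (any(C < 0) || any(C > N)) stop("domain error: C must be in [0, N]")
  C / (M * N) * 1e9
}

#' Quantify annotated tags into per-miRNA RPM records
#'
#' For each miRNA: C is the sum of counts of tags assigned to it (a tag
#' matching several miRNA regions contributes to each), M is the maximum
#' placement multiplicity among its assigned tags (at least 1), and N is the
#' total count of all genome-mapped tags in the library — mRNA-excluded tags
#' still count toward N when genome-mapped. miRNAs with zero reads are absent
#' from the profile. An alternative per-read fractional mode (`m_mode =
#' "per_read"`) assigns each read 1/m to each of its m matched regions with
#' M fixed at 1, which is the brute-force reading of the same definition.
#'
#' @param annotations data.frame from [annotate_tags()].
#' @param m_mode `"max"` (default) or `"per_read"`.
#' @return data.frame: `mirna_id`, `C`, `M`, `N`, `rpm`.
#' @export
quantify <- function(annotations, m_mode = c("max", "per_read")) {
  m_mode <- match.arg(m_mode)
  empty <- data.frame(mirna_id = character(), C = numeric(), M = numeric(),
                      N = numeric(), rpm = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(annotations) == 0) return(empty)
  N <- sum(annotations$count[annotations$n_placements > 0])
  known <- annotations[annotations$category == "known_miRNA", , drop = FALSE]
  if (nrow(known) == 0 || N == 0) return(empty)
  per_tag <- lapply(seq_len(nrow(known)), function(i) {
    ids <- strsplit(known$matched_mirna_ids[i], ",", fixed = TRUE)[[1]]
    data.frame(mirna_id = ids, count = known$count[i],
               multiplicity = known$multiplicity[i],
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, per_tag)
  ids <- sort(unique(d$mirna_id))
  if (m_mode == "max") {
    C <- vapply(ids, function(id) sum(d$count[d$mirna_id == id]), numeric(1))
    M <- vapply(ids, function(id) max(d$multiplicity[d$mirna_id == id]),
                numeric(1))
  } else {
    C <- vapply(ids, function(id) {
      sel <- d$mirna_id == id
      sum(d$count[sel] / pmax(d$multiplicity[sel], 1))
    }, numeric(1))
    M <- rep(1, length(ids))
  }
  data.frame(mirna_id = ids, C = unname(C), M = pmax(unname(M), 1), N = N,
             rpm = rpm(unname(C), pmax(unname(M), 1), N),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fold change between two RPM values
#'
#' `max(rpm_a, floor) / max(rpm_b, floor)`. The floor guards zero-count
#' miRNAs; a natural choice is the RPM of a single uniquely-mapping read,
#' `rpm(1, 1, N)` of the larger library.
#'
#' @param rpm_a,rpm_b non-negative RPM values.
#' @param floor positive pseudo-RPM floor.
#' @return the fold ratio; antisymmetric (`fold(a,b) * fold(b,a) == 1`) when
#'   both values exceed the floor.
#' @export
fold_change <- function(rpm_a, rpm_b, floor = 1e-9) {
  if (any(rpm_a < 0) || any(rpm_b < 0) || floor <= 0)
    stop("domain error: RPM values must be >= 0 and floor > 0")
  pmax(rpm_a, floor) / pmax(rpm_b, floor)
}

#' Call differentially expressed miRNAs by fold threshold
#'
#' Profiles are joined on the union of miRNA ids (missing = 0 RPM). Up:
#' fold >= threshold (a fold of exactly 1.5 is up-regulated, per the
#' inclusive ">= 1.5-fold" rule); down: fold <= 1/threshold.
#'
#' @param profile_a,profile_b data.frames from [quantify()]; `a` is the
#'   numerator condition.
#' @param threshold fold-change threshold (> 1; default 1.5).
#' @param floor pseudo-RPM floor; default `rpm(1, 1, N)` of the larger
#'   library.
#' @param label comparison label.
#' @return list of class `differential_call`: `label`, `up`, `down`
#'   (disjoint id sets), `threshold`, `folds` (data.frame with per-miRNA RPM
#'   pair, fold and direction).
#' @export
call_differential <- function(profile_a, profile_b, threshold = 1.5,
                              floor = NULL, label = "a_vs_b") {
  if (threshold <= 1) stop("config error: threshold must be > 1")
  if (is.null(floor)) {
    Nmax <- max(c(profile_a$N, profile_b$N, 1))
    floor <- rpm(1, 1, Nmax)
  }
  ids <- sort(union(profile_a$mirna_id, profile_b$mirna_id))
  a <- profile_a$rpm[match(ids, profile_a$mirna_id)]
  b <- profile_b$rpm[match(ids, profile_b$mirna_id)]
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  fold <- fold_change(a, b, floor)
  dir <- ifelse(fold >= threshold, "up",
                ifelse(fold <= 1 / threshold, "down", "unchanged"))
  structure(list(label = label,
                 up = ids[dir == "up"], down = ids[dir == "down"],
                 threshold = threshold,
                 folds = data.frame(mirna_id = ids, rpm_a = a, rpm_b = b,
                                    fold = fold, direction = dir,
                                    stringsAsFactors = FALSE)),
            class = "differential_call")
}

#' Check the internal ratio identity of a published fold-table row
#'
#' Each row prints two RPM values (conditions A and B) and their folds versus
#' a common baseline; consistency requires rpm_a/rpm_b == fold_a/fold_b. The
#' relative residual of that identity is returned together with the implied
#' baseline RPM (`rpm_b / fold_b`).
#'
#' @param rpm_a,rpm_b printed RPM values (positive).
#' @param fold_a,fold_b printed folds versus baseline (positive).
#' @param tol residual above which the row is flagged (default 1e-3).
#' @return list: `residual`, `consistent`, `baseline_rpm`.
#' @export
check_table_row <- function(rpm_a, rpm_b, fold_a, fold_b, tol = 1e-3) {
  if (any(c(rpm_a, rpm_b, fold_a, fold_b) <= 0))
    stop("domain error: all printed values must be positive")
  ratio <- fold_a / fold_b
  residual <- abs(rpm_a / rpm_b - ratio) / ratio
  list(residual = residual, consistent = residual <= tol,
       baseline_rpm = rpm_b / fold_b)
}
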