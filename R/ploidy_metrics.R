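# Deterministic ploidy classification from karyotype counts and homeolog
# copy counts, plus genome-size unit conversion (1 pg DNA = 978 Mb).

# somatic chromosome counts with an established ploidy attribution; counts
# outside this set (possible dysploidy) are reported as unknown rather
# than guessed from 2n/2x rounding
.ploidy_lookup <- c(`20` = "2x", `28` = "4x", `38` = "4x", `40` = "4x",
                    `56` = "8x", `60` = "6x", `76` = "8x")

#' Convert a 2C DNA amount to a 1C genome size
#'
#' Uses the flow-cytometry conversion factor 1 pg DNA = 978 Mb, applied to
#' half the 2C value.
#'
#' @param c2_pg 2C DNA amounts in picograms (positive).
#' @return 1C genome sizes in megabases.
#' @examples
#' pg2c_to_mb1c(2.0)   # 978
#' pg2c_to_mb1c(1.99)  # the tomato internal standard -> 973.11
#' @export
pg2c_to_mb1c <- function(c2_pg) {
  stopifnot(is.numeric(c2_pg))
  if (any(!is.na(c2_pg) & c2_pg <= 0))
    stop("2C value must be positive", call. = FALSE)
  c2_pg / 2 * 978
}

#' Classify ploidy from a somatic chromosome count
#'
#' Pure lookup of the established count-to-ploidy attributions (20 is
#' diploid; 28, 38 and 40 tetraploid — 28 and 38 being dysploid
#' derivatives; 56 and 76 octoploid; 60 hexaploid).  Any other count
#' returns `"unknown"`: dysploidy cannot be resolved from the count alone.
#'
#' @param two_n Somatic chromosome counts (positive integers).
#' @return Character vector of calls among `2x, 4x, 6x, 8x, unknown`.
#' @examples
#' classify_ploidy(c(20, 40, 21))
#' @export
classify_ploidy <- function(two_n) {
  stopifnot(is.numeric(two_n))
  if (any(!is.na(two_n) & two_n <= 0))
    stop("chromosome count must be positive", call. = FALSE)
  out <- unname(.ploidy_lookup[as.character(two_n)])
  out[is.na(out) & !is.na(two_n)] <- "unknown"
  out
}

#' Ploidy consensus from per-gene copy counts
#'
#' A taxon is `diploid-like` when every sampled low-copy gene yielded a
#' single sequence, `polyploid-like` when the fraction of genes with two
#' copies reaches `threshold` (default 0.5), and `conflicted` otherwise.
#'
#' @param copies A tibble/data.frame with columns `taxon`, `gene`,
#'   `n_copies` (counts >= 1), one row per taxon-gene pair.
#' @param threshold Fraction of two-copy genes required for a
#'   polyploid-like call.
#' @return A tibble with one row per taxon: `taxon`, `n_genes`,
#'   `frac_two_copies`, `consensus_call`.
#' @export
infer_from_copies <- function(copies, threshold = 0.5) {
  stopifnot(is.data.frame(copies),
            all(c("taxon", "gene", "n_copies") %in% names(copies)))
  if (nrow(copies) == 0L) stop("empty copy-count table", call. = FALSE)
  if (any(copies$n_copies < 1)) stop("copy counts must be >= 1", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(copies, .data$taxon),
    n_genes = dplyr::n(),
    frac_two_copies = mean(.data$n_copies >= 2),
    consensus_call = dplyr::case_when(
      all(.data$n_copies == 1) ~ "diploid-like",
      mean(.data$n_copies >= 2) >= threshold ~ "polyploid-like",
      TRUE ~ "conflicted"),
    .groups = "drop")
}

#' Annotate a karyotype table with genome sizes and ploidy calls
#'
#' @param karyo A tibble/data.frame with columns `taxon`, `two_n` and
#'   optionally `c2_pg`.
#' @return The input with `mb_1c` (when `c2_pg` present) and `ploidy_call`
#'   columns appended.
#' @export
annotate_karyotype <- function(karyo) {
  stopifnot(is.data.frame(karyo), all(c("taxon", "two_n") %in% names(karyo)))
  out <- tibble::as_tibble(karyo)
  if ("c2_pg" %in% names(out)) out$mb_1c <- pg2c_to_mb1c(out$c2_pg)
  out$ploidy_call <- classify_ploidy(out$two_n)
  out
}

#' Joint ploidy call from karyotype and copy-count evidence
#'
#' Combines the karyotype call with the copy-count consensus.  When both
#' sources are present and disagree (e.g. a diploid chromosome count but
#' duplicated gene copies) the karyotype call is reported and a conflict
#' flag is raised; agreement never raises a conflict.
#'
#' @param karyo Karyotype table (see [annotate_karyotype()]); may omit taxa.
#' @param copies Copy-count table (see [infer_from_copies()]); may omit
#'   taxa.
#' @param threshold Passed to [infer_from_copies()].
#' @return A tibble with `taxon`, `ploidy_call`, `consensus_call`,
#'   `joint_call`, `conflict`.
#' @export
consensus_ploidy <- function(karyo = NULL, copies = NULL, threshold = 0.5) {
  if (is.null(karyo) && is.null(copies))
    stop("at least one evidence source is required", call. = FALSE)
  k <- if (!is.null(karyo)) annotate_karyotype(karyo) else
    tibble::tibble(taxon = character(0), ploidy_call = character(0))
  cc <- if (!is.null(copies)) infer_from_copies(copies, threshold) else
    tibble::tibble(taxon = character(0), consensus_call = character(0))
  out <- dplyr::full_join(
    dplyr::select(k, "taxon", "ploidy_call"),
    dplyr::select(cc, "taxon", "consensus_call"),
    by = "taxon")
  karyo_like <- function(call) dplyr::case_when(
    call == "2x" ~ "diploid-like",
    call %in% c("4x", "6x", "8x") ~ "polyploid-like",
    TRUE ~ NA_character_)
  out$conflict <- !is.na(out$ploidy_call) & !is.na(out$consensus_call) &
    !is.na(karyo_like(out$ploidy_call)) &
    out$consensus_call != "conflicted" &
    karyo_like(out$ploidy_call) != out$consensus_call
  out$joint_call <- dplyr::coalesce(out$ploidy_call,
                                    out$consensus_call)
  out
}
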