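#' Herb codes of the five-herb formula
#'
#' @return Character vector of the five herb codes the pipeline accounts for.
#' @export
formula_herbs <- function() c("BGZ", "BZ", "FJ", "WM", "GC")

#' ADME screening configuration
#'
#' Cutoffs for oral bioavailability (OB, percent) and drug-likeness (DL,
#' dimensionless in \[0,1\]). Both must hold jointly for a compound to pass on
#' its pharmacokinetic merits; whitelisted compounds pass regardless. The
#' comparison is inclusive (`>=`) by default.
#'
#' @param ob_min Minimum OB in percent (default 30).
#' @param dl_min Minimum DL (default 0.18).
#' @param inclusive Use `>=` (default) rather than `>` at the cutoffs.
#' @return A `screen_config` list.
#' @export
screen_config <- function(ob_min = 30, dl_min = 0.18, inclusive = TRUE) {
  if (ob_min < 0) stop("ob_min must be >= 0")
  if (dl_min < 0 || dl_min > 1) stop("dl_min must lie in [0, 1]")
  structure(list(ob_min = ob_min, dl_min = dl_min,
                 inclusive = isTRUE(inclusive)),
            class = "screen_config")
}

#' Screen herb ingredients by OB/DL cutoffs with a whitelist override
#'
#' A record is a candidate iff it meets both cutoffs, or is whitelisted
#' (compounds with well-documented pharmacological activity are kept even
#' when their computed OB/DL fall below the cutoffs). The input order is
#' preserved and candidates/rejected partition the input.
#'
#' @param records Compound record data frame (see [read_compound_table()]).
#' @param config A [screen_config()].
#' @return List with elements `candidates` and `rejected` (both compound
#'   record data frames).
#' @export
screen_compounds <- function(records, config = screen_config()) {
  cmp <- if (config$inclusive) `>=` else `>`
  pass <- cmp(records$ob, config$ob_min) & cmp(records$dl, config$dl_min)
  keep <- pass | records$whitelisted
  list(candidates = records[keep, , drop = FALSE],
       rejected = records[!keep, , drop = FALSE],
       n_pass_filter = sum(pass),
       n_whitelisted_rescues = sum(records$whitelisted & !pass))
}

#' Per-herb candidate counts
#'
#' A compound belonging to k herbs contributes 1 to each of its k herbs, so
#' the counts sum to at least the number of candidates.
#'
#' @param candidates Screened compound records.
#' @param herbs Known herb codes; a record carrying any other code is an
#'   error naming the code.
#' @return Named integer vector over `herbs` (zeros included).
#' @export
per_herb_counts <- function(candidates, herbs = formula_herbs()) {
  all_codes <- unlist(candidates$herbs)
  unknown <- setdiff(unique(all_codes), herbs)
  if (length(unknown)) {
    stop(sprintf("unknown herb code: %s", paste(unknown, collapse = ", ")))
  }
  counts <- table(factor(all_codes, levels = herbs))
  stats::setNames(as.integer(counts), herbs)
}

#' Candidates shared by more than one herb
#'
#' @param candidates Screened compound records.
#' @return The subset of records with two or more herb memberships.
#' @export
shared_compounds <- function(candidates) {
  candidates[lengths(candidates$herbs) >= 2L, , drop = FALSE]
}

#' Machine-readable screening summary
#'
#' @param records Full input compound records.
#' @param screened Result of [screen_compounds()].
#' @param herbs Known herb codes.
#' @return List ready for JSON serialisation: input size, pass/rescue/
#'   candidate counts, per-herb counts and number of shared compounds.
#' @export
screen_summary <- function(records, screened, herbs = formula_herbs()) {
  list(n_input = nrow(records),
       n_pass_filter = screened$n_pass_filter,
       n_whitelisted_rescues = screened$n_whitelisted_rescues,
       n_candidates = nrow(screened$candidates),
       per_herb_counts = as.list(per_herb_counts(screened$candidates, herbs)),
       n_shared = nrow(shared_compounds(screened$candidates)))
}
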