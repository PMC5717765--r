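#' Validate a table of per-variant association statistics
#'
#' A variant association table holds one GWAS association per row:
#' variant identifier, effect and other allele (single bases, distinct),
#' optional effect-allele frequency, per-allele effect estimate (beta),
#' its standard error and p-value, and an optional sample size.
#'
#' @param x data.frame with columns \code{variant_id}, \code{effect_allele},
#'   \code{other_allele}, \code{eaf}, \code{beta}, \code{se}, \code{pvalue}
#'   and optionally \code{n}.
#' @return \code{x}, invisibly, after validation.
#' @keywords internal
validate_assoc <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(needed, names(x))
  if (length(miss))
    stop("association table lacks column(s): ", paste(miss, collapse = ", "))
  bad_allele <- !(x$effect_allele %in% BASES) | !(x$other_allele %in% BASES) |
    x$effect_allele == x$other_allele
  if (any(bad_allele))
    stop("invalid allele pair for variant(s): ",
         paste(x$variant_id[bad_allele], collapse = ", "))
  if (any(!is.finite(x$se) | x$se <= 0))
    stop("non-positive SE for variant(s): ",
         paste(x$variant_id[!is.finite(x$se) | x$se <= 0], collapse = ", "))
  if ("pvalue" %in% names(x)) {
    p <- x$pvalue[!is.na(x$pvalue)]
    if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  }
  invisible(x)
}

#' Read a GWAS summary-statistic table
#'
#' Reads a delimited text file (tab or comma separated, header row) with one
#' variant association per row. Column names are mapped onto the canonical
#' set via \code{column_map}, so any dialect with the required content can be
#' read. Rows whose beta or SE cannot be parsed, whose SE is not positive, or
#' whose alleles are not distinct single bases are rejected; a per-row report
#' of rejections is attached as attribute \code{"rejected"} and raised as a
#' warning.
#'
#' @param source path to a delimited text file, or a connection.
#' @param column_map named character vector mapping canonical names
#'   (\code{variant_id}, \code{effect_allele}, \code{other_allele},
#'   \code{eaf}, \code{beta}, \code{se}, \code{pvalue}, \code{n}) to the
#'   column names used in the file. Defaults to the identity mapping.
#' @param sep field separator; \code{NULL} (default) auto-detects tab vs
#'   comma from the header line.
#' @return data.frame with canonical columns, alleles uppercased, one row per
#'   accepted input row (input order preserved). Missing optional columns
#'   (\code{eaf}, \code{pvalue}, \code{n}) are filled with \code{NA}.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("variant_id\teffect_allele\tother_allele\teaf\tbeta\tse\tpvalue",
#'              "rs1\tA\tG\t0.3\t0.10\t0.02\t1e-8"), f)
#' read_summary_table(f)
read_summary_table <- function(source, column_map = NULL, sep = NULL) {
  if (is.character(source) && is.null(sep)) {
    header <- readLines(source, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(source, header = TRUE, sep = sep %||% "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  canon <- c("variant_id", "effect_allele", "other_allele", "eaf",
             "beta", "se", "pvalue", "n")
  map <- stats::setNames(canon, canon)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  absent <- mandatory[!map[mandatory] %in% names(raw)]
  if (length(absent))
    stop("mandatory column(s) not found in input: ",
         paste(map[absent], collapse = ", "))

  out <- data.frame(variant_id = raw[[map["variant_id"]]],
                    effect_allele = toupper(raw[[map["effect_allele"]]]),
                    other_allele = toupper(raw[[map["other_allele"]]]),
                    stringsAsFactors = FALSE)
  num <- function(col) {
    if (map[col] %in% names(raw))
      suppressWarnings(as.numeric(raw[[map[col]]]))
    else rep(NA_real_, nrow(raw))
  }
  out$eaf <- num("eaf")
  out$beta <- num("beta")
  out$se <- num("se")
  out$pvalue <- num("pvalue")
  out$n <- num("n")

  reasons <- character(nrow(out))
  reasons[is.na(out$beta)] <- "unparseable beta"
  reasons[is.na(out$se)] <- "unparseable SE"
  reasons[!is.na(out$se) & out$se <= 0] <- "non-positive SE"
  ok_allele <- out$effect_allele %in% BASES & out$other_allele %in% BASES &
    out$effect_allele != out$other_allele
  reasons[reasons == "" & !ok_allele] <- "invalid allele pair"
  rej <- data.frame(row = which(reasons != ""),
                    variant_id = out$variant_id[reasons != ""],
                    reason = reasons[reasons != ""],
                    stringsAsFactors = FALSE)
  if (nrow(rej))
    warning(nrow(rej), " row(s) rejected: ",
            paste(rej$variant_id, rej$reason, sep = ": ", collapse = "; "))
  out <- out[reasons == "", , drop = FALSE]
  rownames(out) <- NULL
  validate_assoc(out)
  attr(out, "rejected") <- rej
  out
}

#' Write a summary-statistic table
#'
#' Writes in the same dialect \code{\link{read_summary_table}} consumes, at
#' full double precision so that read/write round-trips are bit-identical for
#' finite values.
#'
#' @param x association data.frame.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
write_summary_table <- function(x, path, sep = "\t") {
  cols <- intersect(c("variant_id", "effect_allele", "other_allele", "eaf",
                      "beta", "se", "pvalue", "n"), names(x))
  y <- x[, cols, drop = FALSE]
  for (col in cols)
    if (is.numeric(y[[col]]))
      y[[col]] <- ifelse(is.na(y[[col]]), "NA", sprintf("%.17g", y[[col]]))
  utils::write.table(y, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an instrument set
#'
#' An instrument set is the harmonised per-variant exposure/outcome data a
#' Mendelian randomisation estimator consumes: for each variant, the effect
#' on the exposure (beta_exposure, se_exposure) and on the outcome
#' (beta_outcome, se_outcome), both expressed per copy of the same effect
#' allele. A provenance log records every flip, drop, proxy substitution and
#' filter applied on the way to the set.
#'
#' @param data data.frame with columns \code{variant_id},
#'   \code{beta_exposure}, \code{se_exposure}, \code{beta_outcome},
#'   \code{se_outcome}; optionally \code{pvalue_exposure},
#'   \code{pvalue_outcome}, \code{eaf}.
#' @param risk_factor label for the exposure.
#' @param provenance data.frame log of applied transformations
#'   (columns \code{action}, \code{variant_id}, \code{detail}).
#' @return object of class \code{instrument_set} (a data.frame).
#' @export
instrument_set <- function(data, risk_factor = "exposure",
                           provenance = empty_provenance()) {
  stopifnot(is.data.frame(data))
  needed <- c("variant_id", "beta_exposure", "se_exposure",
              "beta_outcome", "se_outcome")
  miss <- setdiff(needed, names(data))
  if (length(miss))
    stop("instrument set lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) < 1L) stop("instrument set must contain at least 1 variant")
  if (anyDuplicated(data$variant_id))
    stop("duplicate variant_id in instrument set")
  if (any(data$se_exposure <= 0) || any(data$se_outcome <= 0))
    stop("all standard errors must be positive")
  rownames(data) <- NULL
  structure(data,
            risk_factor = risk_factor,
            provenance = provenance,
            class = c("instrument_set", "data.frame"))
}

empty_provenance <- function() {
  data.frame(action = character(), variant_id = character(),
             detail = character(), stringsAsFactors = FALSE)
}

add_provenance <- function(prov, action, ids, detail = "") {
  if (!length(ids)) return(prov)
  rbind(prov, data.frame(action = action, variant_id = as.character(ids),
                         detail = detail, stringsAsFactors = FALSE))
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set for ", attr(x, "risk_factor"), ": ",
      nrow(x), " variant(s)\n", sep = "")
  print.data.frame(x, ...)
  prov <- attr(x, "provenance")
  if (nrow(prov))
    cat("Provenance: ", nrow(prov), " recorded action(s); ",
        "see attr(x, \"provenance\")\n", sep = "")
  invisible(x)
}

#' Harmonise exposure and outcome associations onto a common effect allele
#'
#' In the two-sample design the variant-exposure and variant-outcome
#' associations come from different studies, which need not report effects
#' for the same allele or strand. Harmonisation retains the variants present
#' in both tables and re-expresses every outcome effect per copy of the
#' exposure table's effect allele: when the outcome record's effect allele
#' equals the exposure record's other allele, the outcome beta sign is
#' flipped and its frequency replaced by one minus itself. Allele labels are
#' optionally compared after strand complementing (A-T, C-G) before a pair is
#' declared incompatible.
#'
#' Palindromic variants (A/T or C/G), whose strand cannot be resolved from
#' allele labels, are handled per \code{palindrome_policy}: \code{"drop"}
#' removes them; \code{"frequency_infer"} (default) orients them by comparing
#' the effect-allele frequencies to 0.5 and drops the variant when either
#' frequency falls within \code{eaf_tolerance} of 0.5 (too close to call) or
#' is missing.
#'
#' @param exposure,outcome association data.frames as returned by
#'   \code{\link{read_summary_table}}.
#' @param palindrome_policy \code{"frequency_infer"} or \code{"drop"}.
#' @param eaf_tolerance half-width of the frequency band around 0.5 inside
#'   which a palindromic variant is considered unresolvable (default 0.08,
#'   i.e. drop when either eaf is in 0.42--0.58).
#' @param strand \code{"complement"} (default) to accept allele pairs that
#'   match after strand complementing, or \code{"drop"} to treat them as
#'   incompatible.
#' @param risk_factor label stored on the result.
#' @return an \code{\link{instrument_set}}; its \code{"provenance"} attribute
#'   records every flip and drop with a reason.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("frequency_infer", "drop"),
                      eaf_tolerance = 0.08,
                      strand = c("complement", "drop"),
                      risk_factor = "exposure") {
  palindrome_policy <- match.arg(palindrome_policy)
  strand <- match.arg(strand)
  validate_assoc(exposure); validate_assoc(outcome)
  if (!nrow(exposure) || !nrow(outcome))
    stop("exposure and outcome tables must both be nonempty")

  prov <- empty_provenance()
  common <- intersect(exposure$variant_id, outcome$variant_id)
  prov <- add_provenance(prov, "drop",
                         setdiff(exposure$variant_id, common),
                         "absent from outcome data")
  ex <- exposure[match(common, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(common, outcome$variant_id), , drop = FALSE]

  n <- length(common)
  keep <- rep(TRUE, n)
  flip <- rep(FALSE, n)
  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    if (is_palindromic(ea_x, oa_x)) {
      # Allele labels cannot resolve strand; labels on both sides necessarily
      # match up to swap, so orientation comes from frequency (or the variant
      # is dropped).
      compatible <- (ea_y %in% c(ea_x, oa_x)) && (oa_y %in% c(ea_x, oa_x))
      if (!compatible) {
        keep[i] <- FALSE
        prov <- add_provenance(prov, "drop", common[i], "incompatible alleles")
        next
      }
      if (palindrome_policy == "drop") {
        keep[i] <- FALSE
        prov <- add_provenance(prov, "drop", common[i],
                               "palindromic (policy: drop)")
        next
      }
      fx <- ex$eaf[i]; fy <- ou$eaf[i]
      if (is.na(fx) || is.na(fy) ||
          abs(fx - 0.5) <= eaf_tolerance || abs(fy - 0.5) <= eaf_tolerance) {
        keep[i] <- FALSE
        prov <- add_provenance(prov, "drop", common[i],
                               "palindromic, frequency uninformative")
        next
      }
      flip[i] <- (fx > 0.5) != (fy > 0.5)
      if (flip[i])
        prov <- add_provenance(prov, "flip", common[i],
                               "palindromic, oriented by frequency")
    } else {
      if (ea_y == ea_x && oa_y == oa_x) {
        # identical labelling; nothing to do
      } else if (ea_y == oa_x && oa_y == ea_x) {
        flip[i] <- TRUE
        prov <- add_provenance(prov, "flip", common[i], "allele swap")
      } else if (strand == "complement" &&
                 complement_allele(ea_y) == ea_x &&
                 complement_allele(oa_y) == oa_x) {
        prov <- add_provenance(prov, "relabel", common[i],
                               "strand complement")
      } else if (strand == "complement" &&
                 complement_allele(ea_y) == oa_x &&
                 complement_allele(oa_y) == ea_x) {
        flip[i] <- TRUE
        prov <- add_provenance(prov, "flip", common[i],
                               "strand complement + allele swap")
      } else {
        keep[i] <- FALSE
        prov <- add_provenance(prov, "drop", common[i], "incompatible alleles")
      }
    }
  }

  beta_y <- ifelse(flip, -ou$beta, ou$beta)
  eaf_y <- ifelse(flip, 1 - ou$eaf, ou$eaf)
  dat <- data.frame(variant_id = common,
                    effect_allele = ex$effect_allele,
                    other_allele = ex$other_allele,
                    eaf = ex$eaf,
                    beta_exposure = ex$beta,
                    se_exposure = ex$se,
                    pvalue_exposure = if ("pvalue" %in% names(ex)) ex$pvalue
                                      else NA_real_,
                    beta_outcome = beta_y,
                    se_outcome = ou$se,
                    pvalue_outcome = if ("pvalue" %in% names(ou)) ou$pvalue
                                     else NA_real_,
                    eaf_outcome = eaf_y,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (!nrow(dat))
    stop("no variants remain after harmonisation")
  instrument_set(dat, risk_factor = risk_factor, provenance = prov)
}

#' Substitute proxy variants for index variants absent from the outcome data
#'
#' When an instrument is missing from the outcome study, a proxy in high
#' linkage disequilibrium (r-squared above 0.9) can stand in for it: the
#' proxy's outcome association is relabelled with the index variant's
#' identifier. Variants whose proxy is also absent simply remain missing.
#'
#' @param outcome outcome association data.frame.
#' @param wanted character vector of index variant identifiers.
#' @param proxies data.frame with columns \code{index_id}, \code{proxy_id},
#'   \code{r2} (each r2 must exceed 0.9), as read by
#'   \code{\link{read_proxy_map}}.
#' @return the outcome table restricted to wanted variants, with proxies
#'   relabelled; attribute \code{"substitutions"} is a data.frame logging
#'   each substitution.
#' @export
apply_proxy_map <- function(outcome, wanted, proxies) {
  validate_assoc(outcome)
  if (nrow(proxies) && any(proxies$r2 <= 0.9))
    stop("proxy r2 values must all exceed 0.9")
  missing_ids <- setdiff(wanted, outcome$variant_id)
  subs <- proxies[proxies$index_id %in% missing_ids &
                  proxies$proxy_id %in% outcome$variant_id, , drop = FALSE]
  # one proxy per index: keep the highest-r2 entry
  if (nrow(subs)) {
    subs <- subs[order(subs$index_id, -subs$r2), , drop = FALSE]
    subs <- subs[!duplicated(subs$index_id), , drop = FALSE]
  }
  out <- outcome[outcome$variant_id %in% wanted, , drop = FALSE]
  if (nrow(subs)) {
    prox_rows <- outcome[match(subs$proxy_id, outcome$variant_id), ,
                         drop = FALSE]
    prox_rows$variant_id <- subs$index_id
    out <- rbind(out, prox_rows)
  }
  out <- out[order(match(out$variant_id, wanted)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "substitutions") <-
    data.frame(index_id = subs$index_id, proxy_id = subs$proxy_id,
               r2 = subs$r2, stringsAsFactors = FALSE)
  out
}

#' Prune correlated instruments to near-independence
#'
#' Greedy selection in ascending p-value order: a candidate variant is kept
#' if and only if its r-squared with every already-kept variant is below the
#' threshold, so that among correlated variants the one with the lowest
#' p-value for association with the risk factor survives. Ties on p-value
#' are broken by variant identifier in lexical order, making the selection
#' deterministic.
#'
#' @param candidates association data.frame with a \code{pvalue} column.
#' @param ld symmetric matrix of pairwise r-squared values with variant
#'   identifiers as dimnames; must cover every candidate.
#' @param r2_threshold exclusion threshold (default 0.2).
#' @return the kept subset of \code{candidates}, in original input order.
#' @export
prune_ld <- function(candidates, ld, r2_threshold = 0.2) {
  validate_assoc(candidates)
  if (!all(candidates$variant_id %in% rownames(ld)))
    stop("LD matrix does not cover variant(s): ",
         paste(setdiff(candidates$variant_id, rownames(ld)), collapse = ", "))
  validate_ld_matrix(ld)
  ord <- order(candidates$pvalue, candidates$variant_id)
  kept <- character(0)
  for (i in ord) {
    id <- candidates$variant_id[i]
    if (!length(kept) || all(ld[id, kept] < r2_threshold))
      kept <- c(kept, id)
  }
  out <- candidates[candidates$variant_id %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_ld_matrix <- function(ld) {
  stopifnot(is.matrix(ld))
  if (is.null(rownames(ld)) || !identical(rownames(ld), colnames(ld)))
    stop("LD matrix needs identical row and column variant identifiers")
  if (!isTRUE(all.equal(ld, t(ld), tolerance = 1e-8)))
    stop("LD matrix must be symmetric")
  if (any(abs(diag(ld) - 1) > 1e-8)) stop("LD matrix diagonal must be 1")
  if (any(ld < 0 | ld > 1 + 1e-12)) stop("r2 entries must lie in [0, 1]")
  invisible(ld)
}

#' Read a square LD (r-squared) matrix from delimited text
#'
#' Expects a header row of variant identifiers and an identifier column.
#'
#' @param path delimited text file.
#' @param sep field separator (default tab).
#' @return numeric matrix with variant dimnames.
#' @export
read_ld_matrix <- function(path, sep = "\t") {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                                   row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  validate_ld_matrix(m)
  m
}

#' Read a proxy map from delimited text
#'
#' Three columns: \code{index_id}, \code{proxy_id}, \code{r2}.
#'
#' @param path delimited text file.
#' @param sep field separator (default tab).
#' @return data.frame with those three columns.
#' @export
read_proxy_map <- function(path, sep = "\t") {
  p <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("index_id", "proxy_id", "r2") %in% names(p)))
  if (nrow(p) && any(p$r2 <= 0.9))
    stop("proxy r2 values must all exceed 0.9")
  p
}
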