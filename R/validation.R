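#' Read a per-sample validation summary table
#'
#' CSV with one row per tumor sample and, for each rearrangement type
#' (`deletion`, `inversion`, `translocation`), the four columns
#' `<type>_attempted`, `<type>_non_validated`, `<type>_constitutional`,
#' `<type>_somatic`. The packaged fixture
#' (`inst/extdata/validation_summary.csv`) transcribes the validation
#' counts of a 15-tumor hormone-receptor-negative breast cancer mate-pair
#' cohort.
#'
#' @param path CSV path; default the packaged fixture.
#' @return data.frame of validation counts.
#' @export
read_validation_summary <- function(path = NULL) {
  path <- path %||% matesv_extdata("validation_summary.csv")
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

validation_types <- c("deletion", "inversion", "translocation")

#' Aggregate a validation summary into cohort totals
#'
#' Checks the per-row invariant
#' `attempted = non_validated + constitutional + somatic` for every type,
#' then aggregates: totals per type and overall, the somatic /
#' constitutional split, the constitutional (germline) fraction of
#' validated translocations, the interchromosomal fraction of somatic
#' events, and the interchromosomal : intrachromosomal somatic ratio
#' (translocations / (deletions + inversions)).
#'
#' @param tab data.frame in the [read_validation_summary()] schema (may
#'   have zero rows: all totals are then 0 and ratios `NA`).
#' @return A list of class `validation_summary`: `per_type` (data.frame),
#'   `attempted`, `validated`, `non_validated`, `constitutional`,
#'   `somatic`, `somatic_by_type`, `constitutional_by_type`,
#'   `translocation_constitutional_fraction`,
#'   `deletion_constitutional_fraction`,
#'   `interchromosomal_somatic_fraction`, `inter_intra_ratio`.
#' @export
summarize_validation <- function(tab) {
  need <- as.vector(outer(validation_types,
                          c("attempted", "non_validated", "constitutional",
                            "somatic"), paste, sep = "_"))
  if (!all(need %in% names(tab)))
    stop_msg("validation table missing columns: %s",
             paste(setdiff(need, names(tab)), collapse = ", "))

  for (ty in validation_types) {
    att <- tab[[paste0(ty, "_attempted")]]
    s <- tab[[paste0(ty, "_non_validated")]] +
         tab[[paste0(ty, "_constitutional")]] + tab[[paste0(ty, "_somatic")]]
    bad <- which(att != s)
    if (length(bad))
      stop_msg("row %d (%s): %s attempted (%d) != non_validated + constitutional + somatic (%d)",
               bad[1], tab$sample[bad[1]] %||% "?", ty, att[bad[1]], s[bad[1]])
  }

  per_type <- do.call(rbind, lapply(validation_types, function(ty) {
    att <- sum(tab[[paste0(ty, "_attempted")]])
    nv <- sum(tab[[paste0(ty, "_non_validated")]])
    co <- sum(tab[[paste0(ty, "_constitutional")]])
    so <- sum(tab[[paste0(ty, "_somatic")]])
    data.frame(type = ty, attempted = att, non_validated = nv,
               validated = att - nv, constitutional = co, somatic = so)
  }))

  tot <- function(col) sum(per_type[[col]])
  somatic_by_type <- stats::setNames(per_type$somatic, per_type$type)
  const_by_type <- stats::setNames(per_type$constitutional, per_type$type)
  frac <- function(num, den) if (den > 0) num / den else NA_real_

  tra <- per_type[per_type$type == "translocation", ]
  del <- per_type[per_type$type == "deletion", ]
  structure(list(
    per_type = per_type,
    attempted = tot("attempted"),
    validated = tot("validated"),
    non_validated = tot("non_validated"),
    constitutional = tot("constitutional"),
    somatic = tot("somatic"),
    somatic_by_type = somatic_by_type,
    constitutional_by_type = const_by_type,
    translocation_constitutional_fraction =
      frac(tra$constitutional, tra$validated),
    deletion_constitutional_fraction = frac(del$constitutional,
                                            del$validated),
    interchromosomal_somatic_fraction =
      frac(somatic_by_type[["translocation"]], tot("somatic")),
    inter_intra_ratio =
      frac(somatic_by_type[["translocation"]],
           somatic_by_type[["deletion"]] + somatic_by_type[["inversion"]])),
    class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("validation_summary: attempted %d / validated %d / somatic %d\n",
              x$attempted, x$validated, x$somatic))
  print(x$per_type, row.names = FALSE)
  invisible(x)
}

#' Read the packaged somatic-SV breakpoint/gene table
#'
#' One row per sequence-validated somatic rearrangement of the bundled
#' 15-tumor cohort: sample, type, the two 1-based breakpoints, and the
#' printed disrupted-gene labels (semicolon-separated
#' `"SYMBOL (exon k)"` / `"SYMBOL (intron k-(k+1))"`, empty when no gene
#' is hit).
#'
#' @param path TSV path; default the packaged fixture.
#' @return data.frame with columns `sample_id`, `type`, `chrom1`,
#'   `breakpoint1`, `chrom2`, `breakpoint2`, `disrupted_genes`.
#' @export
read_sv_table <- function(path = NULL) {
  path <- path %||% matesv_extdata("somatic_svs.tsv")
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, fill = TRUE,
                          colClasses = c("character", "character",
                                         "character", "numeric", "character",
                                         "numeric", "character"))
  df$disrupted_genes[is.na(df$disrupted_genes)] <- ""
  df
}

#' Path to a packaged example/fixture file
#'
#' @param file File name under the package `extdata` directory; with no
#'   argument, lists the available files.
#' @return Full path (or a character vector of file names).
#' @export
matesv_extdata <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "matesv")))
  path <- system.file("extdata", file, package = "matesv")
  if (path == "") stop_msg("no packaged file '%s'", file)
  path
}
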