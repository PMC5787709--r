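#' Read per-root cell-length profiles from a long-format table
#'
#' Reads a CSV or TSV file (by extension) with one row per measured cell
#' and columns \code{root_id}, \code{genotype}, \code{day}, \code{tissue},
#' \code{cell_index}, \code{cell_length_um}, \code{is_first_hair} (0/1),
#' validates it and returns one [measured_profile()] per root, ordered by
#' cell index. Duplicate \code{(root_id, cell_index)} pairs, non-positive
#' lengths and mixed tissues within one root are hard errors that name the
#' offending rows.
#'
#' @param path File path (.csv or .tsv/.txt).
#' @return Named list of [measured_profile()] objects.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty profile file: ", path)
  validate_profile_table(df)
  profiles_as_list(df)
}

validate_profile_table <- function(df) {
  need <- c("root_id", "genotype", "day", "tissue", "cell_index",
            "cell_length_um", "is_first_hair")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$cell_length_um) | df$cell_length_um <= 0)
  if (length(bad))
    stop("non-positive cell length at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  dup <- duplicated(df[c("root_id", "cell_index")])
  if (any(dup))
    stop("duplicate (root_id, cell_index) at row(s): ",
         paste(utils::head(which(dup), 10), collapse = ", "))
  mixed <- tapply(df$tissue, df$root_id, function(x) length(unique(x)) > 1)
  if (any(mixed))
    stop("mixed tissues within root(s): ",
         paste(names(mixed)[mixed], collapse = ", "))
  invisible(df)
}

## long-format table -> list of measured_profile
profiles_as_list <- function(df) {
  validate_profile_table(df)
  lapply(split(df, df$root_id), function(d) {
    d <- d[order(d$cell_index), ]
    hair <- which(d$is_first_hair == 1)
    measured_profile(d$cell_length_um,
                     first_hair_index = if (length(hair)) min(hair)
                                        else nrow(d) + 1L,
                     root_id = d$root_id[1], genotype = d$genotype[1],
                     day = d$day[1], tissue = d$tissue[1])
  })
}

#' Write a synthetic cohort (or a bare profile table) to disk
#'
#' Writes the long-format profile table, the ground-truth manifest (when
#' present) and a provenance block (preset, seed, noise level, package
#' version) as plain-text files inside \code{dir}.
#'
#' @param cohort A \code{"synthetic_cohort"} or a profile data frame.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (inherits(cohort, "synthetic_cohort")) {
    p1 <- file.path(dir, "profiles.csv")
    utils::write.csv(cohort$profiles, p1, row.names = FALSE)
    p2 <- file.path(dir, "manifest.csv")
    utils::write.csv(cohort$manifest, p2, row.names = FALSE)
    p3 <- file.path(dir, "provenance.txt")
    writeLines(c(paste("preset:", cohort$preset$name),
                 paste("seed:", cohort$seed),
                 paste("noise_cv:", cohort$noise_cv),
                 paste("package: rootzone",
                       as.character(utils::packageVersion("rootzone")))),
               p3)
    paths <- c(p1, p2, p3)
  } else {
    validate_profile_table(cohort)
    p1 <- file.path(dir, "profiles.csv")
    utils::write.csv(cohort, p1, row.names = FALSE)
    paths <- p1
  }
  invisible(paths)
}

#' Write / read a per-root trait table
#'
#' Thin CSV wrappers so trait tables round-trip losslessly between
#' pipeline stages.
#'
#' @param traits Trait table.
#' @param path CSV path.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export a mechanism report as structured JSON
#'
#' Serializes a [mechanism_report()] — relation statistics, verdict,
#' trace and the optional five-trait comparison — without external JSON
#' dependencies (the writer emits a fixed, documented schema).
#'
#' @param report A \code{"mechanism_report"}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mechanism_report"))
  esc <- function(s) gsub('"', '\\\\"', s)
  num <- function(x) ifelse(is.na(x), "null", formatC(x, digits = 12,
                                                      format = "g"))
  rel <- report$relations
  rel_json <- paste(vapply(seq_len(nrow(rel)), function(i) sprintf(
    '    {"relation": "%s", "method": "%s", "estimate": %s, "p_value": %s, "n": %d, "slope": %s, "slope_se": %s}',
    rel$relation[i], rel$method[i], num(rel$estimate[i]),
    num(rel$p_value[i]), rel$n[i], num(rel$slope[i]), num(rel$slope_se[i])),
    ""), collapse = ",\n")
  cmp_json <- if (is.null(report$comparison)) "null" else {
    cm <- report$comparison
    paste0("[\n", paste(vapply(seq_len(nrow(cm)), function(i) sprintf(
      '    {"trait": "%s", "p_value": %s, "skipped": %s}',
      cm$trait[i], num(cm$p_value[i]),
      tolower(as.character(cm$skipped[i]))), ""), collapse = ",\n"),
      sprintf('\n  ],\n  "pass": %s', tolower(attr(cm, "pass"))))
  }
  json <- sprintf(paste0(
    '{\n  "n": %d,\n  "verdict": "%s",\n  "trace": [\n%s\n  ],\n',
    '  "relations": [\n%s\n  ],\n  "comparison": %s\n}\n'),
    report$n, report$verdict$verdict,
    paste(sprintf('    "%s"', esc(report$verdict$trace)), collapse = ",\n"),
    rel_json, cmp_json)
  writeLines(json, path)
  invisible(path)
}
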