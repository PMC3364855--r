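# Tabular input/output: plate-format viability tables, GMT gene-set
# collections, expression matrices, and generic result tables.

DOSE_UNIT_FACTORS <- c(nM = 1e-3, uM = 1, mM = 1e3)

#' Parse doses with an optional unit suffix into canonical micromolar
#'
#' Doses anywhere in the pipeline are held in micromolar (uM). Values may be
#' plain numbers (interpreted in `default_unit`) or carry an `nM`/`uM`/`mM`
#' suffix; conversion happens once, at ingest, and is exact for the
#' power-of-ten factors involved.
#'
#' @param x Numeric vector, or character vector like `"10nM"`, `"1 uM"`.
#' @param default_unit Unit assumed when a value has no suffix
#'   (`"nM"`, `"uM"` or `"mM"`).
#' @return Numeric vector of doses in uM.
#' @examples
#' parse_dose(c("1uM", "10nM", "0.5"))
#' @export
parse_dose <- function(x, default_unit = "uM") {
  default_unit <- normalize_unit(default_unit)
  if (is.numeric(x)) {
    return(x * DOSE_UNIT_FACTORS[[default_unit]])
  }
  x <- trimws(as.character(x))
  pat <- "^([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)\\s*([a-zA-ZµμM]*)$"
  m <- regexec(pat, x)
  parts <- regmatches(x, m)
  bad <- lengths(parts) == 0L
  if (any(bad)) {
    abort_format(sprintf(
      "Cannot parse dose value(s): %s",
      paste(utils::head(x[bad], 3L), collapse = ", ")
    ))
  }
  num <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  unit <- vapply(parts, function(p) p[4], character(1))
  unit[unit == ""] <- default_unit
  unit <- vapply(unit, normalize_unit, character(1))
  unname(num * DOSE_UNIT_FACTORS[unit])
}

normalize_unit <- function(u) {
  u <- gsub("µ|μ", "u", u)
  if (!u %in% names(DOSE_UNIT_FACTORS)) {
    abort_format(sprintf("Unknown dose unit '%s' (expected nM, uM or mM).", u))
  }
  u
}

#' Describe the columns and control tags of a plate table
#'
#' The screen's plate layout (which wells hold untreated, scrambled-siRNA and
#' drug-only controls) is file-specific, so it is declared explicitly per
#' file rather than assumed.
#'
#' @param plate,well,gene,sirna,dose,replicate,signal Column names in the
#'   source file.
#' @param control_tags Reserved gene-column tags marking control wells.
#' @param dose_unit Unit assumed for doses without a suffix.
#' @param delim Field delimiter; `NULL` sniffs comma vs tab from the header.
#' @return A list of class `plate_schema`.
#' @export
plate_schema <- function(plate = "plate", well = "well", gene = "gene",
                         sirna = "sirna_id", dose = "dose",
                         replicate = "replicate", signal = "signal",
                         control_tags = c("UNTREATED", "SCRAMBLE", "DRUG_ONLY"),
                         dose_unit = "uM", delim = NULL) {
  structure(
    list(
      plate = plate, well = well, gene = gene, sirna = sirna, dose = dose,
      replicate = replicate, signal = signal,
      control_tags = toupper(control_tags),
      dose_unit = dose_unit, delim = delim
    ),
    class = "plate_schema"
  )
}

#' Read a plate-format viability table
#'
#' Reads one raw readout per well of a luminescence viability assay
#' (plate, well, gene or control tag, siRNA id, drug dose, replicate,
#' signal). Gene symbols are uppercased at ingest and doses converted to
#' canonical uM; rows whose gene column carries a reserved control tag are
#' flagged and their siRNA id cleared.
#'
#' @param source Path to a CSV/TSV file (or a connection readr accepts).
#' @param schema A [plate_schema()] mapping column names and control tags.
#' @return A tibble of well measurements with columns `plate_id`, `well`,
#'   `gene`, `sirna_id`, `dose` (uM), `replicate`, `signal`, `is_control`.
#' @export
read_plate_table <- function(source, schema = plate_schema()) {
  delim <- schema$delim %||% sniff_delim(source)
  raw <- readr::read_delim(source, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  needed <- c(plate = schema$plate, well = schema$well, gene = schema$gene,
              dose = schema$dose, replicate = schema$replicate,
              signal = schema$signal)
  missing_cols <- setdiff(unname(needed), names(raw))
  if (length(missing_cols) > 0L) {
    abort_format(sprintf(
      "Plate table is missing mandatory column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    plate_id  = as.character(raw[[schema$plate]]),
    well      = toupper(as.character(raw[[schema$well]])),
    gene      = toupper(as.character(raw[[schema$gene]])),
    sirna_id  = if (schema$sirna %in% names(raw)) {
      as.character(raw[[schema$sirna]])
    } else {
      NA_character_
    },
    dose      = parse_dose(raw[[schema$dose]], schema$dose_unit),
    replicate = as.integer(raw[[schema$replicate]]),
    signal    = as.numeric(raw[[schema$signal]])
  )
  neg <- which(!is.na(out$signal) & out$signal < 0)
  if (length(neg) > 0L) {
    abort_validation(sprintf(
      "Negative signal at row(s): %s", paste(utils::head(neg, 5L), collapse = ", ")
    ))
  }
  if (any(out$dose < 0, na.rm = TRUE)) {
    abort_validation("Doses must be non-negative.")
  }
  dup <- duplicated(out[c("plate_id", "well")])
  if (any(dup)) {
    abort_validation(sprintf(
      "Duplicated (plate, well) pair(s), first at row %d.", which(dup)[1]
    ))
  }
  out$is_control <- out$gene %in% schema$control_tags
  out$sirna_id[out$is_control] <- NA_character_
  out
}

sniff_delim <- function(source) {
  header <- readLines(source, n = 1L)
  if (length(header) == 0L) return(",")
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a GMT gene-set collection
#'
#' Standard Broad-dialect GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`. Member symbols are uppercased;
#' duplicates within a line are collapsed with a warning.
#'
#' @param source Path to a GMT file.
#' @return A named list of class `gene_set_collection`; each element is a
#'   list with `description` and `genes`.
#' @export
read_gmt <- function(source) {
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      abort_format(sprintf(
        "GMT line %d has %d field(s); at least 3 (name, description, members) required.",
        i, length(fields)
      ))
    }
    name <- fields[1]
    members <- toupper(fields[-(1:2)])
    members <- members[nzchar(members)]
    uniq <- unique(members)
    if (length(uniq) < length(members)) {
      rlang::warn(sprintf(
        "Gene set '%s': %d duplicate member symbol(s) collapsed.",
        name, length(members) - length(uniq)
      ))
    }
    sets[[name]] <- list(description = fields[2], genes = uniq)
  }
  structure(sets, class = "gene_set_collection")
}

#' Build a gene-set collection in code
#'
#' @param sets Named list of character vectors (member symbols).
#' @param descriptions Optional named character vector of descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  out <- lapply(names(sets), function(nm) {
    genes <- unique(toupper(sets[[nm]]))
    if (length(genes) == 0L) {
      abort_validation(sprintf("Gene set '%s' is empty.", nm))
    }
    list(description = descriptions[nm] %||% "", genes = genes)
  })
  names(out) <- names(sets)
  structure(out, class = "gene_set_collection")
}

as_gene_set_collection <- function(x) {
  if (inherits(x, "gene_set_collection")) return(x)
  if (is.character(x)) x <- list(set = x)
  gene_set_collection(x)
}

#' Construct a log2 expression matrix with sample conditions
#'
#' @param values Numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns (colnames = labels).
#' @param condition Named character vector mapping each sample to
#'   `"treated"` or `"control"`.
#' @return A list of class `expression_matrix`.
#' @export
expression_matrix <- function(values, condition) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_validation("Expression values need gene rownames and sample colnames.")
  }
  if (anyNA(rownames(values)) || any(!nzchar(rownames(values)))) {
    abort_validation("Missing gene symbols in expression matrix.")
  }
  condition <- condition[colnames(values)]
  if (anyNA(condition)) {
    abort_config("Every sample must be present in the condition map.")
  }
  if (!all(condition %in% c("treated", "control"))) {
    abort_config("Conditions must be 'treated' or 'control'.")
  }
  if (sum(condition == "treated") < 1L || sum(condition == "control") < 1L) {
    abort_validation("Need at least one treated and one control sample.")
  }
  rownames(values) <- toupper(rownames(values))
  structure(
    list(values = values, genes = rownames(values),
         samples = colnames(values), condition = condition),
    class = "expression_matrix"
  )
}

#' Read a genes-by-samples log2 expression table
#'
#' First column holds gene symbols; every remaining column must appear in
#' `condition_map`. Duplicate gene rows are resolved by the configured rule
#' (default: keep the row with the highest mean, reported via a message).
#'
#' @param source Path to a TSV file.
#' @param condition_map Named character vector: sample -> "treated"/"control".
#' @param dup_rule How to resolve duplicated gene symbols; only
#'   `"max_mean"` is implemented.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(source, condition_map, dup_rule = "max_mean") {
  dup_rule <- match.arg(dup_rule, "max_mean")
  raw <- readr::read_tsv(source, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2L) {
    abort_format("Expression table needs a gene column plus at least one sample.")
  }
  samples <- names(raw)[-1]
  absent <- setdiff(samples, names(condition_map))
  if (length(absent) > 0L) {
    abort_config(sprintf(
      "Sample(s) absent from condition map: %s", paste(absent, collapse = ", ")
    ))
  }
  genes <- toupper(as.character(raw[[1]]))
  vals <- as.matrix(raw[-1])
  storage.mode(vals) <- "double"
  if (anyDuplicated(genes)) {
    means <- rowMeans(vals)
    keep <- order(genes, -means)
    keep <- keep[!duplicated(genes[keep])]
    message(sprintf(
      "%d duplicated gene row(s) resolved by keeping the max-mean row.",
      length(genes) - length(keep)
    ))
    keep <- sort(keep)
    genes <- genes[keep]
    vals <- vals[keep, , drop = FALSE]
  }
  rownames(vals) <- genes
  expression_matrix(vals, condition_map)
}

#' Write a result table as TSV
#'
#' Column order is preserved as given (deterministic); numeric values are
#' written at full precision so a read-back reproduces them to better than
#' 1e-12 relative.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `records`, invisibly.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  flat <- records
  for (nm in names(flat)) {
    if (is.list(flat[[nm]])) {
      flat[[nm]] <- vapply(
        flat[[nm]],
        function(x) paste(format(x, digits = 17, trim = TRUE), collapse = ";"),
        character(1)
      )
    }
  }
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(records)
}
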