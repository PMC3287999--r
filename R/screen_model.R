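#' @keywords internal
"_PACKAGE"

# Well roles recognised throughout the pipeline. Edge wells are PBS-filled
# buffers and never carry measurements into any analysis stage.
WELL_ROLES <- c("sample", "neg_control", "pos_control", "transfection_only",
                "edge_excluded")

PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12

#' Default 96-well screening plate layout
#'
#' Builds the layout used throughout the screen: the 36 outer wells (rows A
#' and H, columns 1 and 12) are PBS-filled and excluded from analysis; the
#' duplicated controls sit in fixed inner positions (negative / scrambled
#' siRNA at B2-B3, positive / PPARG siRNA at C2-C3, transfection-reagent-only
#' at D2-D3); the remaining 54 inner wells hold one library siRNA each.
#'
#' Control positions within the inner wells are an arbitrary but fixed,
#' documented convention; any fixed placement yields the same statistics
#' because no downstream step uses well coordinates.
#'
#' @return A data frame with columns `row` (letter A-H), `col` (integer
#'   1-12) and `role`, one row per well (96 rows).
#' @examples
#' layout <- build_default_layout()
#' table(layout$role)
#' @export
build_default_layout <- function() {
  layout <- expand.grid(row = PLATE_ROWS, col = PLATE_COLS,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  layout <- layout[order(layout$row, layout$col), ]
  rownames(layout) <- NULL
  edge <- layout$row %in% c("A", "H") | layout$col %in% c(1, 12)
  layout$role <- ifelse(edge, "edge_excluded", "sample")
  ctrl <- list(neg_control = list(row = "B", col = c(2, 3)),
               pos_control = list(row = "C", col = c(2, 3)),
               transfection_only = list(row = "D", col = c(2, 3)))
  for (role in names(ctrl)) {
    sel <- layout$row == ctrl[[role]]$row & layout$col %in% ctrl[[role]]$col
    layout$role[sel] <- role
  }
  layout
}

#' Read a plate-level well table
#'
#' Parses a plate-reader export in the screen's CSV dialect (UTF-8, comma
#' separated, dot decimal) into one record per well. Numeric fields that do
#' not parse are kept as `NA` and flagged `missing` rather than dropped, so
#' QC reports can account for them. Edge wells are flagged `excluded` and
#' their readouts ignored.
#'
#' @param path Path to a CSV file with header columns
#'   `plate_id,row,col,role,sirna_id,gene_id,lipid,dna`.
#' @return A data frame of well measurements with columns `plate_id`, `row`,
#'   `col`, `role`, `sirna_id`, `gene_id`, `lipid_raw`, `dna_raw`,
#'   `lipid_corrected` (initially `NA`) and `qc_flag`
#'   (`ok`/`missing`/`excluded`).
#' @seealso [write_plate_table()]
#' @export
load_plate_table <- function(path) {
  if (!file.exists(path)) {
    stop("plate file not found: ", path)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  required <- c("plate_id", "row", "col", "role", "sirna_id", "gene_id",
                "lipid", "dna")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("plate table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  wells <- data.frame(
    plate_id = raw$plate_id,
    row = raw$row,
    col = suppressWarnings(as.integer(raw$col)),
    role = raw$role,
    sirna_id = ifelse(raw$sirna_id == "", NA_character_, raw$sirna_id),
    gene_id = ifelse(raw$gene_id == "", NA_character_, raw$gene_id),
    lipid_raw = suppressWarnings(as.numeric(raw$lipid)),
    dna_raw = suppressWarnings(as.numeric(raw$dna)),
    stringsAsFactors = FALSE
  )
  bad_role <- setdiff(unique(wells$role), WELL_ROLES)
  if (length(bad_role) > 0) {
    stop("plate table format error: unknown role(s) ",
         paste(bad_role, collapse = ", "))
  }
  key <- paste(wells$plate_id, wells$row, wells$col, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("plate layout error: duplicate well ", dup)
  }
  wells$lipid_corrected <- NA_real_
  wells$qc_flag <- ifelse(wells$role == "edge_excluded", "excluded",
                   ifelse(is.na(wells$lipid_raw) | is.na(wells$dna_raw),
                          "missing", "ok"))
  neg <- which(wells$qc_flag == "ok" &
               (wells$lipid_raw < 0 | wells$dna_raw < 0))
  if (length(neg) > 0) {
    warning(length(neg), " well(s) with negative readouts flagged missing")
    wells$qc_flag[neg] <- "missing"
  }
  wells
}

#' Write a plate-level well table
#'
#' Inverse of [load_plate_table()]: writes the raw readout columns in the
#' exchange dialect. Corrected values and QC flags are derived quantities and
#' are not part of the exchange format.
#'
#' @param wells Well data frame as returned by [load_plate_table()] or
#'   [simulate_screen()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(wells, path) {
  out <- data.frame(
    plate_id = wells$plate_id,
    row = wells$row,
    col = wells$col,
    role = wells$role,
    sirna_id = ifelse(is.na(wells$sirna_id), "", wells$sirna_id),
    gene_id = ifelse(is.na(wells$gene_id), "", wells$gene_id),
    lipid = ifelse(is.na(wells$lipid_raw), "",
                   format(wells$lipid_raw, digits = 15, trim = TRUE,
                          scientific = FALSE)),
    dna = ifelse(is.na(wells$dna_raw), "",
                 format(wells$dna_raw, digits = 15, trim = TRUE,
                        scientific = FALSE)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a screening library annotation table
#'
#' Generates the gene-to-siRNA mapping for a screen phase with the standard
#' three independent siRNA sequences per gene.
#'
#' @param n_genes Number of genes in the library.
#' @param phase `"primary"` or `"validation"`; validation libraries carry new
#'   sequences, so their siRNA identifiers are disjoint from the primary ones.
#' @param gene_ids Optional explicit gene identifiers (length `n_genes`).
#' @return Data frame with columns `gene_id`, `sirna_id`, `phase`.
#' @export
make_library <- function(n_genes, phase = c("primary", "validation"),
                         gene_ids = NULL) {
  phase <- match.arg(phase)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("G%05d", seq_len(n_genes))
  }
  stopifnot(length(gene_ids) == n_genes)
  tag <- if (phase == "primary") "s" else "v"
  data.frame(
    gene_id = rep(gene_ids, each = 3),
    sirna_id = paste0(rep(gene_ids, each = 3), "_", tag, rep(1:3, n_genes)),
    phase = phase,
    stringsAsFactors = FALSE
  )
}

#' Validate a screening library
#'
#' Report-only check of the library structure: every gene must carry exactly
#' three siRNAs and siRNA identifiers must be unique within a phase. The
#' full-scale primary library (7,784 genes) must come out at 23,352 unique
#' siRNAs.
#'
#' @param lib Library data frame (`gene_id`, `sirna_id`, optional `phase`).
#' @return A list with `n_genes`, `n_sirnas_unique`, `genes_wrong_count`
#'   (data frame of offending genes and their siRNA counts),
#'   `duplicated_sirnas` (character) and `n_violations`.
#' @export
validate_library <- function(lib) {
  stopifnot(all(c("gene_id", "sirna_id") %in% names(lib)))
  if (nrow(lib) == 0) {
    return(list(n_genes = 0L, n_sirnas_unique = 0L,
                genes_wrong_count = data.frame(gene_id = character(),
                                               n_sirnas = integer()),
                duplicated_sirnas = character(), n_violations = 0L))
  }
  counts <- table(lib$gene_id)
  wrong <- counts[counts != 3]
  genes_wrong <- data.frame(gene_id = names(wrong),
                            n_sirnas = as.integer(wrong),
                            stringsAsFactors = FALSE)
  dup <- unique(lib$sirna_id[duplicated(lib$sirna_id)])
  list(
    n_genes = length(counts),
    n_sirnas_unique = length(unique(lib$sirna_id)),
    genes_wrong_count = genes_wrong,
    duplicated_sirnas = dup,
    n_violations = nrow(genes_wrong) + length(dup)
  )
}
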