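#' Default column map for BioMart-style gene tables
#'
#' Maps the internal field names onto the column headers of the input
#' table. The defaults match the plain names used by the package's own
#' writers and the simulator; BioMart exports can be read by passing the
#' export's header strings (e.g. `gene_id = "Gene stable ID"`).
#'
#' @param ... overrides, e.g. `chrom = "Chromosome/scaffold name"`.
#' @return Named character vector internal-name -> input column header.
#' @export
default_column_map <- function(...) {
  map <- c(gene_id = "gene_id", symbol = "symbol", chrom = "chrom",
           start = "start", end = "end", strand = "strand",
           biotype = "biotype")
  dots <- c(...)
  map[names(dots)] <- dots
  map
}

#' Parse a gene-annotation table
#'
#' Reads a tab-separated gene table (BioMart convention: 1-based inclusive
#' coordinates, strand as +/- or 1/-1) into the package's internal gene
#' records, which use 0-based half-open coordinates. Entries on
#' alternative scaffolds are flagged, not dropped; pseudogene status is
#' taken from the biotype column when present.
#'
#' @param x file path or data.frame.
#' @param column_map see [default_column_map()].
#' @param chrom_sizes optional named vector of primary-assembly chromosome
#'   lengths; when given, any chromosome absent from it is flagged as an
#'   alternative scaffold. Without it a name-pattern heuristic is used
#'   (PATCH/CHR_/GL/KI/JH/scaffold).
#' @return data.frame with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `pseudogene`, `on_alt_scaffold`,
#'   `biotype`.
#' @export
parse_gene_table <- function(x, column_map = default_column_map(),
                             chrom_sizes = NULL) {
  df <- if (is.character(x)) {
    read.delim(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               check.names = FALSE)
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  required <- c("gene_id", "chrom", "start", "end", "strand")
  for (field in required) {
    if (!(column_map[[field]] %in% names(df))) {
      stop("required column '", column_map[[field]], "' (", field,
           ") missing from gene table")
    }
  }
  if (nrow(df) == 0) return(empty_gene_records())

  get <- function(field, default = NULL) {
    col <- column_map[[field]]
    if (!is.null(col) && !is.na(col) && col %in% names(df)) df[[col]] else default
  }
  start_in <- suppressWarnings(as.numeric(get("start")))
  end_in <- suppressWarnings(as.numeric(get("end")))
  bad <- which(is.na(start_in) | is.na(end_in))
  if (length(bad)) {
    stop("non-numeric coordinate in gene table at data row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  strand_in <- as.character(get("strand"))
  strand <- ifelse(strand_in %in% c("+", "1", "+1"), "+",
                   ifelse(strand_in %in% c("-", "-1"), "-", NA_character_))
  if (anyNA(strand)) {
    stop("unrecognized strand value at data row(s) ",
         paste(head(which(is.na(strand)), 5), collapse = ", "))
  }
  chrom <- as.character(get("chrom"))
  biotype <- as.character(get("biotype", default = rep("", nrow(df))))
  on_alt <- if (!is.null(chrom_sizes)) {
    !(chrom %in% names(chrom_sizes))
  } else {
    grepl("PATCH|^CHR_|^GL[0-9]|^KI[0-9]|^JH[0-9]|scaffold|_random$|_alt$",
          chrom, ignore.case = FALSE)
  }
  symbol <- as.character(get("symbol", default = as.character(get("gene_id"))))
  symbol[is.na(symbol) | symbol == ""] <- as.character(get("gene_id"))[is.na(symbol) | symbol == ""]

  rec <- data.frame(
    gene_id = as.character(get("gene_id")),
    symbol = symbol,
    chrom = chrom,
    start = start_in - 1,          # BioMart 1-based inclusive -> 0-based half-open
    end = end_in,
    strand = strand,
    pseudogene = grepl("pseudogene", biotype, ignore.case = TRUE),
    on_alt_scaffold = on_alt,
    biotype = biotype,
    stringsAsFactors = FALSE
  )
  if (any(rec$start >= rec$end)) {
    stop("gene with start >= end at data row(s) ",
         paste(head(which(rec$start >= rec$end), 5), collapse = ", "))
  }
  rec
}

empty_gene_records <- function() {
  data.frame(gene_id = character(), symbol = character(), chrom = character(),
             start = numeric(), end = numeric(), strand = character(),
             pseudogene = logical(), on_alt_scaffold = logical(),
             biotype = character(), stringsAsFactors = FALSE)
}

#' Default symbol-pattern family rules
#'
#' First-match-wins regular expressions on gene symbols assigning each
#' record to a chemoreceptor family. The selection query behind public
#' annotation is not standardized, so the rules are plain data and can be
#' edited or replaced wholesale.
#'
#' @param species one of "mouse", "rat", "human".
#' @return data.frame with columns `pattern`, `family`.
#' @export
default_family_rules <- function(species = c("mouse", "rat", "human")) {
  species <- match.arg(species)
  rules <- switch(species,
    mouse = list(
      c("^Olfr",              "OR"),
      c("^Taar",              "TAAR"),
      c("^Vmn1r",             "V1R"),
      c("^Vmn2r",             "V2R"),
      c("^Fpr",               "FPR"),
      c("^Tr[abgd][vdjc]",    "TCR")
    ),
    rat = list(
      c("^Olr",               "OR"),
      c("^Taar",              "TAAR"),
      c("^Vom1r",             "V1R"),
      c("^Vom2r",             "V2R"),
      c("^Fpr",               "FPR"),
      c("^Tr[abgd][vdjc]",    "TCR")
    ),
    human = list(
      c("^OR[0-9]+[A-Z]",     "OR"),
      c("^TAAR",              "TAAR"),
      c("^VN1R",              "V1R"),
      c("^VN2R",              "V2R"),
      c("^FPR",               "FPR"),
      c("^TR[ABGD][VDJC]",    "TCR")
    )
  )
  data.frame(pattern = vapply(rules, `[`, "", 1),
             family = vapply(rules, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Assign chemoreceptor families by symbol pattern
#'
#' @param symbols character vector of gene symbols.
#' @param rules data.frame of (pattern, family), first match wins; see
#'   [default_family_rules()].
#' @return character vector of families; "other" where no rule matches.
#' @export
classify_family <- function(symbols, rules = default_family_rules("mouse")) {
  fam <- rep("other", length(symbols))
  unset <- rep(TRUE, length(symbols))
  for (i in seq_len(nrow(rules))) {
    hit <- unset & grepl(rules$pattern[i], symbols, ignore.case = FALSE)
    fam[hit] <- rules$family[i]
    unset[hit] <- FALSE
  }
  fam
}

#' Families belonging to each grouped list
#' @param list_type one of "MOE", "VNO", "olfactome", "TCR".
#' @return character vector of family names.
#' @export
list_families <- function(list_type = c("MOE", "VNO", "olfactome", "TCR")) {
  list_type <- match.arg(list_type)
  switch(list_type,
    MOE = c("OR", "TAAR"),
    VNO = c("V1R", "V2R", "FPR"),
    olfactome = c("OR", "TAAR", "V1R", "V2R", "FPR"),
    TCR = "TCR")
}

#' Assemble a grouped, sorted gene list
#'
#' Classifies records into families (unless a `family` column is already
#' present), prunes alternative-scaffold entries, keeps the families of
#' the requested list, optionally removes pseudogene-flagged entries and
#' sorts by natural chromosome order then start.
#'
#' @param records output of [parse_gene_table()].
#' @param species "mouse", "rat" or "human" (chooses default rules).
#' @param list_type "MOE", "VNO", "olfactome" or "TCR".
#' @param include_pseudo keep pseudogene-flagged entries?
#' @param rules family rules; defaults to [default_family_rules()] for
#'   `species`.
#' @return data.frame of gene records (class `gene_list`) with a `family`
#'   column; attributes `species`, `list_type`, `include_pseudo`.
#' @export
build_gene_list <- function(records, species = "mouse",
                            list_type = c("MOE", "VNO", "olfactome", "TCR"),
                            include_pseudo = TRUE,
                            rules = default_family_rules(species)) {
  list_type <- match.arg(list_type)
  if (is.null(records$family)) {
    records$family <- classify_family(records$symbol, rules)
  }
  keep <- !records$on_alt_scaffold &
    records$family %in% list_families(list_type)
  if (!include_pseudo) keep <- keep & !records$pseudogene
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("gene list '", list_type, "' is empty after filtering")
  }
  out <- out[order_genomic(out), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("gene_list", "data.frame"),
            species = species, list_type = list_type,
            include_pseudo = include_pseudo)
}

#' Write / read a normalized gene-list TSV
#'
#' The on-disk representation uses the 1-based inclusive coordinates of
#' the input convention, so a written table parses back to identical
#' records (round-trip).
#'
#' @param genes gene records (internal 0-based coordinates).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- data.frame(
    gene_id = genes$gene_id, symbol = genes$symbol, chrom = genes$chrom,
    start = as.integer(genes$start) + 1L, end = as.integer(genes$end),
    strand = genes$strand, biotype = genes$biotype,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
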