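# Minimal GenBank flat-file reader: LOCUS id, FEATURES block, ORIGIN sequence.
# Parses the location grammar needed for organelle records: plain spans,
# complement(...), join(...) and order(...) (arbitrarily nested); remote
# references and fuzzy bounds (<, >) are simplified to their numeric bounds.

# Feature kinds retained in the feature table; everything else (source,
# misc_feature, ...) is dropped.
GB_KEEP_KINDS <- c("gene", "CDS", "tRNA", "rRNA", "intron", "exon", "spacer")

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) stop("not a GenBank flat file (no LOCUS line): ", path,
                            call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  purrr::map2(starts, ends, function(s, e) parse_genbank_record(lines[s:e]))
}

parse_genbank_record <- function(lines) {
  locus <- stringr::str_split(stringr::str_squish(lines[[1]]), " ")[[1]]
  id <- locus[[2]]
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) {
    acc <- stringr::str_split(stringr::str_squish(acc_line[[1]]), " ")[[1]][2]
    if (!is.na(acc) && nzchar(acc)) id <- acc
  }

  origin_at <- grep("^ORIGIN", lines)
  if (!length(origin_at)) stop("GenBank record '", id, "' has no ORIGIN block",
                               call. = FALSE)
  seq_lines <- lines[(origin_at[[1]] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_at <- grep("^FEATURES", lines)
  features <- NULL
  if (length(feat_at)) {
    block <- lines[(feat_at[[1]] + 1L):(origin_at[[1]] - 1L)]
    features <- parse_genbank_features(block)
  }
  list(id = id, seq = seq, features = features)
}

parse_genbank_features <- function(block) {
  # A feature starts at column 6 with a key; continuation/qualifier lines are
  # indented to column 22.
  is_key <- grepl("^ {5}\\S", block)
  if (!any(is_key)) return(NULL)
  idx <- cumsum(is_key)
  feats <- split(block[idx > 0], idx[idx > 0])
  rows <- purrr::map_dfr(feats, function(fl) {
    key <- stringr::str_split(stringr::str_squish(fl[[1]]), " ")[[1]][1]
    if (!key %in% GB_KEEP_KINDS) return(NULL)
    # location may continue over lines until the first qualifier (/...)
    body <- stringr::str_trim(c(stringr::str_remove(fl[[1]], "^ {5}\\S+\\s*"), fl[-1]))
    qual_at <- grep("^/", body)
    loc_end <- if (length(qual_at)) qual_at[[1]] - 1L else length(body)
    loc <- paste(body[seq_len(loc_end)], collapse = "")
    quals <- body[grep("^/", body)]
    name <- gb_qualifier(quals, "gene")
    if (is.na(name)) name <- gb_qualifier(quals, "standard_name")
    if (is.na(name)) name <- key
    spans <- parse_gb_location(loc)
    if (is.null(spans)) return(NULL)
    spans$kind <- key
    spans$name <- name
    spans
  })
  if (!nrow(rows)) return(NULL)
  rows[, c("kind", "name", "start", "end", "strand")]
}

gb_qualifier <- function(quals, what) {
  hit <- grep(paste0("^/", what, "="), quals, value = TRUE)
  if (!length(hit)) return(NA_character_)
  gsub('^/[^=]+="?|"$', "", hit[[1]])
}

# Parse a GenBank location string into a tibble of (start, end, strand) rows.
parse_gb_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  parse1 <- function(loc, strand) {
    if (grepl("^complement\\(", loc)) {
      inner <- sub("^complement\\((.*)\\)$", "\\1", loc)
      return(parse1(inner, if (strand == "+") "-" else "+"))
    }
    if (grepl("^(join|order)\\(", loc)) {
      inner <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
      parts <- split_gb_args(inner)
      return(purrr::map_dfr(parts, parse1, strand = strand))
    }
    loc <- gsub("[<>]", "", loc)
    if (grepl(":", loc, fixed = TRUE)) return(NULL)  # remote reference
    nums <- suppressWarnings(as.integer(stringr::str_split(loc, "\\.\\.|\\^")[[1]]))
    if (anyNA(nums)) return(NULL)
    tibble(start = nums[[1]], end = nums[[length(nums)]], strand = strand)
  }
  parse1(loc, "+")
}

# Split comma-separated location arguments at parenthesis depth 0.
split_gb_args <- function(x) {
  chars <- seq_chars(x)
  depth <- cumsum((chars == "(") - (chars == ")"))
  grp <- cumsum(chars == "," & depth == 0)
  parts <- vapply(split(chars, grp), chars_to_seq, character(1))
  unname(sub("^,", "", parts))
}
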