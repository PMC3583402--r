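#' Circular genome geometry
#'
#' Container for the geometry of a circular chromosome: strand-annotated
#' genes, promoters with exclusion footprints, protein-factor binding sites
#' (e.g. mTERF) with directional passage probabilities, and optional
#' G-quadruplex terminator sites.
#'
#' Coordinates are stored 0-based, half-open, and are interpreted modulo
#' `length` (an interval may run across the origin, in which case its stored
#' `end` exceeds `length`). File readers convert from the 1-based inclusive
#' convention of GenBank/GFF/TSV input. Heavy-strand transcription moves
#' toward increasing coordinates, light-strand toward decreasing ones.
#'
#' @param length chromosome length in nucleotides.
#' @param genes data frame with columns `name`, `start`, `end`, `strand`
#'   (0-based half-open internal coordinates; `strand` is `"heavy"` or
#'   `"light"`). `NULL` for none.
#' @param promoters data frame with columns `name`, `tss`, `strand` and
#'   optionally `fp_start`, `fp_end` (footprint; defaults to -15..+1 around
#'   the TSS in transcription direction, 17 nt).
#' @param factor_sites data frame with columns `name`, `start`, `end`,
#'   `pass_prob_heavy`, `pass_prob_light`, `binding_intensity`.
#' @param quadruplex_sites data frame with columns `name`, `start`, `end`,
#'   `strand`, `termination_probability`.
#' @param name label for the genome.
#' @param circular must be `TRUE`; kept explicit because the model is defined
#'   on circular DNA only.
#'
#' @return an object of class `mt_geometry`.
#' @export
mt_geometry <- function(length, genes = NULL, promoters = NULL,
                        factor_sites = NULL, quadruplex_sites = NULL,
                        name = "genome", circular = TRUE) {
  if (!isTRUE(circular))
    stop("only circular chromosomes are supported")
  length <- as.numeric(length)
  if (length(length) != 1L || !is.finite(length) || length < 1)
    stop("'length' must be a single positive number of nucleotides")

  g <- structure(
    list(length = length, circular = TRUE, name = as.character(name),
         genes = .norm_feature_frame(genes, length,
                                     c("name", "start", "end", "strand")),
         promoters = .norm_promoters(promoters, length),
         factor_sites = .norm_factor_sites(factor_sites, length),
         quadruplex_sites = .norm_quadruplex(quadruplex_sites, length)),
    class = "mt_geometry")
  validate_geometry(g)
}

# empty typed frames so downstream code never special-cases NULL
.empty_frame <- function(cols, types) {
  out <- lapply(types, function(tp) vector(tp, 0L))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

.norm_strand <- function(s) {
  s <- as.character(s)
  s[s %in% c("+", "H", "h")] <- "heavy"
  s[s %in% c("-", "L", "l")] <- "light"
  if (!all(s %in% c("heavy", "light")))
    stop("strand must be 'heavy' or 'light' (or +/-)")
  s
}

# normalize an interval so start lies in [0, L) and end in (start, start + L]
.norm_interval <- function(start, end, L) {
  span <- (end - start) %% L
  span[span == 0 & end != start] <- L
  start <- start %% L
  list(start = start, end = start + span)
}

.norm_feature_frame <- function(df, L, cols) {
  if (is.null(df) || NROW(df) == 0L)
    return(.empty_frame(cols, c("character", "numeric", "numeric", "character")))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("name", "start", "end", "strand") %in% names(df)))
    stop("gene table needs columns name, start, end, strand")
  iv <- .norm_interval(as.numeric(df$start), as.numeric(df$end), L)
  data.frame(name = as.character(df$name), start = iv$start, end = iv$end,
             strand = .norm_strand(df$strand), stringsAsFactors = FALSE)
}

.norm_promoters <- function(df, L) {
  cols <- c("name", "tss", "strand", "fp_start", "fp_end")
  if (is.null(df) || NROW(df) == 0L)
    return(.empty_frame(cols, c("character", "numeric", "character",
                                "numeric", "numeric")))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("name", "tss", "strand") %in% names(df)))
    stop("promoter table needs columns name, tss, strand")
  strand <- .norm_strand(df$strand)
  tss <- as.numeric(df$tss) %% L
  if (is.null(df$fp_start) || is.null(df$fp_end)) {
    # default footprint: -15..+1 relative to the TSS in transcription
    # direction (17 nt), the assumed phage-type polymerase occupancy
    dir <- ifelse(strand == "heavy", 1, -1)
    fp_start <- ifelse(dir == 1, tss - 15, tss - 1)
    fp_end <- fp_start + 17
  } else {
    fp_start <- as.numeric(df$fp_start)
    fp_end <- as.numeric(df$fp_end)
  }
  iv <- .norm_interval(fp_start, fp_end, L)
  out <- data.frame(name = as.character(df$name), tss = tss, strand = strand,
                    fp_start = iv$start, fp_end = iv$end,
                    stringsAsFactors = FALSE)
  # the TSS must sit inside the footprint (modulo L)
  inside <- ((out$tss - out$fp_start) %% L) < (out$fp_end - out$fp_start)
  if (!all(inside))
    stop("promoter TSS outside its footprint: ",
         paste(out$name[!inside], collapse = ", "))
  out
}

.norm_factor_sites <- function(df, L) {
  cols <- c("name", "start", "end", "pass_prob_heavy", "pass_prob_light",
            "binding_intensity")
  if (is.null(df) || NROW(df) == 0L)
    return(.empty_frame(cols, c("character", rep("numeric", 5))))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$end)) df$end <- as.numeric(df$start) + 28  # mTERF ~28 bp
  iv <- .norm_interval(as.numeric(df$start), as.numeric(df$end), L)
  out <- data.frame(name = as.character(df$name),
                    start = iv$start, end = iv$end,
                    pass_prob_heavy = as.numeric(df$pass_prob_heavy),
                    pass_prob_light = as.numeric(df$pass_prob_light),
                    binding_intensity = as.numeric(df$binding_intensity),
                    stringsAsFactors = FALSE)
  bad <- out$pass_prob_heavy < 0 | out$pass_prob_heavy > 1 |
    out$pass_prob_light < 0 | out$pass_prob_light > 1
  if (any(bad)) stop("factor passage probabilities must lie in [0, 1]")
  if (any(out$binding_intensity < 0))
    stop("factor binding intensities must be >= 0")
  if (any(out$end - out$start < 1)) stop("factor site width must be >= 1 nt")
  out
}

.norm_quadruplex <- function(df, L) {
  cols <- c("name", "start", "end", "strand", "termination_probability")
  if (is.null(df) || NROW(df) == 0L)
    return(.empty_frame(cols, c("character", "numeric", "numeric",
                                "character", "numeric")))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  iv <- .norm_interval(as.numeric(df$start), as.numeric(df$end), L)
  out <- data.frame(name = as.character(df$name),
                    start = iv$start, end = iv$end,
                    strand = .norm_strand(df$strand),
                    termination_probability =
                      as.numeric(df$termination_probability),
                    stringsAsFactors = FALSE)
  if (any(out$termination_probability < 0 | out$termination_probability > 1))
    stop("quadruplex termination probabilities must lie in [0, 1]")
  out
}

#' Validate a genome geometry
#'
#' Checks the structural invariants: coordinates inside `[0, length)` after
#' normalization, strands valid, no two promoters sharing a (TSS, strand)
#' pair, and no overlapping promoter footprints on the same strand.
#'
#' @param g an `mt_geometry`.
#' @return `g`, invisibly unchanged, or an error.
#' @export
validate_geometry <- function(g) {
  stopifnot(inherits(g, "mt_geometry"))
  L <- g$length
  chk <- function(x, what) {
    if (any(x < 0 | x >= L))
      stop(what, " coordinate outside [0, length) after normalization")
  }
  chk(g$genes$start, "gene")
  chk(g$promoters$tss, "promoter TSS")
  chk(g$factor_sites$start, "factor site")
  chk(g$quadruplex_sites$start, "quadruplex site")

  key <- paste(g$promoters$tss, g$promoters$strand)
  if (anyDuplicated(key))
    stop("two promoters share the same (TSS, strand)")
  invisible(g)
}

# overlapping same-strand footprints are legitimate in real genomes (the
# frog LSP2A/LSP2B pair overlaps); the toy constructor refuses them so
# synthetic studies stay unambiguous
.check_promoter_overlap <- function(g) {
  L <- g$length
  for (s in c("heavy", "light")) {
    p <- g$promoters[g$promoters$strand == s, , drop = FALSE]
    if (nrow(p) > 1L) {
      for (i in seq_len(nrow(p) - 1L)) for (j in seq(i + 1L, nrow(p))) {
        if (.circ_overlap(p$fp_start[i], p$fp_end[i],
                          p$fp_start[j], p$fp_end[j], L))
          stop("overlapping promoter footprints on the same strand: ",
               p$name[i], ", ", p$name[j])
      }
    }
  }
  invisible(g)
}

# do two circular intervals [a1, a2) and [b1, b2) (a1, b1 in [0, L)) overlap?
.circ_overlap <- function(a1, a2, b1, b2, L) {
  # shift so interval a starts at 0; then b overlaps iff it starts before a
  # ends, or wraps around past L into [0, a2 - a1)
  off <- (b1 - a1) %% L
  alen <- a2 - a1
  blen <- b2 - b1
  off < alen || (off + blen) > L
}

#' @export
print.mt_geometry <- function(x, ...) {
  cat(sprintf("Circular genome '%s': %d nt\n", x$name, round(x$length)))
  cat(sprintf("  genes: %d (%d heavy / %d light)\n", nrow(x$genes),
              sum(x$genes$strand == "heavy"), sum(x$genes$strand == "light")))
  if (nrow(x$promoters))
    cat("  promoters:",
        paste(sprintf("%s@%d(%s)", x$promoters$name,
                      round(x$promoters$tss) + 1L,
                      substr(x$promoters$strand, 1, 1)), collapse = " "), "\n")
  if (nrow(x$factor_sites))
    cat("  factor sites:",
        paste(sprintf("%s[%d-%d] p=%.4g q=%.4g", x$factor_sites$name,
                      round(x$factor_sites$start) + 1L,
                      round(x$factor_sites$end),
                      x$factor_sites$pass_prob_heavy,
                      x$factor_sites$pass_prob_light), collapse = " "), "\n")
  if (nrow(x$quadruplex_sites))
    cat("  quadruplex sites:", nrow(x$quadruplex_sites), "\n")
  invisible(x)
}

#' Build a toy circular genome from explicit specs
#'
#' Deterministic constructor used for synthetic-data studies and tests. Specs
#' use 1-based inclusive coordinates (as in the TSV dialect) and are
#' converted internally.
#'
#' @param length genome length (nt).
#' @param promoter_specs list of lists with `name`, `tss` (1-based),
#'   `strand`.
#' @param gene_specs list of lists with `name`, `start`, `end` (1-based
#'   inclusive), `strand`.
#' @param factor_specs list of lists with `name`, `start` (1-based), optional
#'   `end`, `p`, `q`, `lambda`.
#' @param quadruplex_specs list of lists with `name`, `start`, `end`,
#'   `strand`, `prob`.
#' @param name genome label.
#' @return an `mt_geometry`.
#' @export
make_toy_genome <- function(length, promoter_specs = list(),
                            gene_specs = list(), factor_specs = list(),
                            quadruplex_specs = list(), name = "toy") {
  promoters <- if (length(promoter_specs))
    data.frame(name = vapply(promoter_specs, `[[`, "", "name"),
               tss = vapply(promoter_specs, function(p) p$tss, 0) - 1,
               strand = vapply(promoter_specs, `[[`, "", "strand"),
               stringsAsFactors = FALSE)
  genes <- if (length(gene_specs))
    data.frame(name = vapply(gene_specs, `[[`, "", "name"),
               start = vapply(gene_specs, function(p) p$start, 0) - 1,
               end = vapply(gene_specs, function(p) p$end, 0),
               strand = vapply(gene_specs, `[[`, "", "strand"),
               stringsAsFactors = FALSE)
  factors <- if (length(factor_specs))
    data.frame(name = vapply(factor_specs, `[[`, "", "name"),
               start = vapply(factor_specs, function(p) p$start, 0) - 1,
               end = vapply(factor_specs,
                            function(p) if (is.null(p$end)) p$start + 27 else p$end, 0),
               pass_prob_heavy = vapply(factor_specs, function(p) p$p, 0),
               pass_prob_light = vapply(factor_specs, function(p) p$q, 0),
               binding_intensity = vapply(factor_specs, function(p) p$lambda, 0),
               stringsAsFactors = FALSE)
  quads <- if (length(quadruplex_specs))
    data.frame(name = vapply(quadruplex_specs, `[[`, "", "name"),
               start = vapply(quadruplex_specs, function(p) p$start, 0) - 1,
               end = vapply(quadruplex_specs, function(p) p$end, 0),
               strand = vapply(quadruplex_specs, `[[`, "", "strand"),
               termination_probability =
                 vapply(quadruplex_specs, function(p) p$prob, 0),
               stringsAsFactors = FALSE)
  g <- mt_geometry(length, genes = genes, promoters = promoters,
                   factor_sites = factors, quadruplex_sites = quads,
                   name = name)
  .check_promoter_overlap(g)
}

# ---------------------------------------------------------------------------
# TSV dialect
#
# header:  #length=<N> circular=1 [name=<label>]
# rows:    feature_type  name  start  end  strand  extra(key=value;...)
# start/end are 1-based inclusive; start > end means the feature spans the
# origin. Promoter rows store the footprint in start/end and carry tss=<pos>
# in extra; factor rows carry p=, q=, lambda=; quadruplex rows carry prob=.
# ---------------------------------------------------------------------------

#' Read a circular genome geometry from file
#'
#' @param path file path.
#' @param format `"tsv"` (the package's own geometry dialect), `"gff3"`
#'   (genes only, via rtracklayer), or `"genbank"` (genes only, minimal
#'   flat-file reader). Promoters and factor sites for GFF3/GenBank input are
#'   supplied by merging a TSV overlay, see `merge_geometry()`.
#' @param length genome length; required for GFF3 files lacking a
#'   `##sequence-region` directive.
#' @return an `mt_geometry`.
#' @export
read_geometry <- function(path, format = c("tsv", "gff3", "genbank"),
                          length = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         tsv = .read_geometry_tsv(path),
         gff3 = .read_geometry_gff3(path, length),
         genbank = .read_geometry_genbank(path))
}

.read_geometry_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[[1]], "#length="))
    stop("geometry TSV parse error: missing '#length=' header in ", path)
  hdr <- strsplit(sub("^#", "", lines[[1]]), "[ \t]+")[[1]]
  kv <- strsplit(hdr, "=", fixed = TRUE)
  hmap <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  L <- as.numeric(hmap[["length"]])
  gname <- if (!is.na(hmap["name"])) hmap[["name"]] else
    sub("\\.[^.]*$", "", basename(path))

  body <- lines[-1][!startsWith(lines[-1], "#")]
  rows <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(rows) < 5L)
  if (length(bad))
    stop("geometry TSV parse error at data row ", bad[1], " of ", path)

  f <- function(i) vapply(rows, `[`, "", i)
  type <- f(1); nm <- f(2)
  start1 <- as.numeric(f(3)); end1 <- as.numeric(f(4)); strand <- f(5)
  extra <- vapply(rows, function(r) if (length(r) >= 6L) r[[6]] else "", "")
  if (any(is.na(start1) | is.na(end1)))
    stop("geometry TSV parse error: non-numeric coordinate in ", path)
  if (any(start1 < 1 | start1 > L | end1 < 1 | end1 > L))
    stop("coordinate outside [1, length] in ", path)

  ex <- lapply(extra, .parse_extra)
  exnum <- function(i, key) {
    v <- ex[[i]][[key]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  # 1-based inclusive -> 0-based half-open (end1 is already the half-open end)
  sel <- function(tp) which(type == tp)

  i <- sel("gene")
  genes <- if (length(i))
    data.frame(name = nm[i], start = start1[i] - 1, end = .incl_end(start1[i], end1[i], L),
               strand = strand[i], stringsAsFactors = FALSE)
  i <- sel("promoter")
  promoters <- if (length(i))
    data.frame(name = nm[i],
               tss = vapply(seq_along(i), function(k) exnum(i[k], "tss"), 0) - 1,
               strand = strand[i],
               fp_start = start1[i] - 1,
               fp_end = .incl_end(start1[i], end1[i], L),
               stringsAsFactors = FALSE)
  i <- sel("factor")
  factors <- if (length(i))
    data.frame(name = nm[i], start = start1[i] - 1,
               end = .incl_end(start1[i], end1[i], L),
               pass_prob_heavy = vapply(seq_along(i), function(k) exnum(i[k], "p"), 0),
               pass_prob_light = vapply(seq_along(i), function(k) exnum(i[k], "q"), 0),
               binding_intensity = vapply(seq_along(i), function(k) exnum(i[k], "lambda"), 0),
               stringsAsFactors = FALSE)
  i <- sel("quadruplex")
  quads <- if (length(i))
    data.frame(name = nm[i], start = start1[i] - 1,
               end = .incl_end(start1[i], end1[i], L), strand = strand[i],
               termination_probability =
                 vapply(seq_along(i), function(k) exnum(i[k], "prob"), 0),
               stringsAsFactors = FALSE)

  mt_geometry(L, genes = genes, promoters = promoters, factor_sites = factors,
              quadruplex_sites = quads, name = gname)
}

# half-open end for a 1-based inclusive (start, end) pair on a circle
.incl_end <- function(start1, end1, L) {
  span <- (end1 - start1 + 1) %% L
  span[span == 0] <- L
  (start1 - 1) + span
}

.parse_extra <- function(s) {
  if (!nzchar(s) || s == ".") return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
}

#' Write a geometry in the TSV dialect
#'
#' The writer is the exact inverse of the TSV reader: `read_geometry()` of
#' the written file reproduces the geometry.
#'
#' @param g an `mt_geometry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(g, path) {
  stopifnot(inherits(g, "mt_geometry"))
  L <- g$length
  to1 <- function(start, end) {
    # 0-based half-open -> 1-based inclusive (wrap encoded as start > end)
    s1 <- (start %% L) + 1
    e1 <- ((end - 1) %% L) + 1
    list(s = s1, e = e1)
  }
  lines <- sprintf("#length=%d circular=1 name=%s", round(L), g$name)
  row <- function(type, name, s, e, strand, extra = ".")
    sprintf("%s\t%s\t%d\t%d\t%s\t%s", type, name, round(s), round(e), strand, extra)
  gn <- g$genes
  if (nrow(gn)) {
    iv <- to1(gn$start, gn$end)
    lines <- c(lines, row("gene", gn$name, iv$s, iv$e, gn$strand))
  }
  pr <- g$promoters
  if (nrow(pr)) {
    iv <- to1(pr$fp_start, pr$fp_end)
    lines <- c(lines, row("promoter", pr$name, iv$s, iv$e, pr$strand,
                          sprintf("tss=%d", round(pr$tss) + 1L)))
  }
  fs <- g$factor_sites
  if (nrow(fs)) {
    iv <- to1(fs$start, fs$end)
    lines <- c(lines, row("factor", fs$name, iv$s, iv$e, "both",
                          sprintf("p=%.17g;q=%.17g;lambda=%.17g",
                                  fs$pass_prob_heavy, fs$pass_prob_light,
                                  fs$binding_intensity)))
  }
  qs <- g$quadruplex_sites
  if (nrow(qs)) {
    iv <- to1(qs$start, qs$end)
    lines <- c(lines, row("quadruplex", qs$name, iv$s, iv$e, qs$strand,
                          sprintf("prob=%.17g", qs$termination_probability)))
  }
  writeLines(lines, path)
  invisible(path)
}

.read_geometry_gff3 <- function(path, length = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.null(length)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (length(sl) >= 1L && !is.na(sl[[1]])) {
      length <- sl[[1]]
    } else {
      # fall back to the ##sequence-region directive
      hdr <- grep("^##sequence-region", readLines(path, n = 100L),
                  value = TRUE)
      if (!length(hdr))
        stop("GFF3 lacks a sequence-region length; pass 'length'")
      length <- as.numeric(utils::tail(strsplit(hdr[[1]], "[ \t]+")[[1]], 1))
    }
  }
  keep <- as.character(gr$type) %in% c("gene", "tRNA", "rRNA")
  gr <- gr[keep]
  nm <- gr$Name
  if (is.null(nm)) nm <- gr$ID
  if (is.null(nm)) nm <- paste0("gene", seq_along(gr))
  nm <- ifelse(is.na(nm), paste0("gene", seq_along(gr)), nm)
  genes <- data.frame(name = as.character(nm),
                      start = BiocGenerics::start(gr) - 1,
                      end = BiocGenerics::end(gr),
                      strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-",
                                      "light", "heavy"),
                      stringsAsFactors = FALSE)
  mt_geometry(length, genes = genes,
              name = sub("\\.[^.]*$", "", basename(path)))
}

# minimal GenBank flat-file reader: LOCUS length plus gene/tRNA/rRNA features
.read_geometry_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("GenBank parse error: no LOCUS line in ", path)
  L <- suppressWarnings(as.numeric(sub(".*?(\\d+)\\s+bp.*", "\\1", locus[[1]])))
  if (is.na(L)) stop("GenBank parse error: cannot read length from LOCUS line")
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) stop("GenBank parse error: no FEATURES block in ", path)
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) else length(lines) + 1L
  feat <- lines[(fstart[1] + 1L):(fend - 1L)]

  keys <- grepl("^ {5}\\S", feat)
  idx <- cumsum(keys)
  recs <- split(feat, idx)
  genes <- list()
  for (r in recs) {
    key <- sub("^ {5}(\\S+).*", "\\1", r[[1]])
    if (!key %in% c("gene", "tRNA", "rRNA")) next
    loc <- sub("^ {5}\\S+\\s+", "", r[[1]])
    strand <- if (grepl("complement", loc)) "light" else "heavy"
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
    if (length(nums) < 2L)
      stop("GenBank parse error: unsupported location '", loc, "'")
    a <- as.numeric(nums[[1]]); b <- as.numeric(nums[[length(nums)]])
    qual <- grep("/(gene|product)=", r, value = TRUE)
    nm <- if (length(qual))
      sub('.*=(\"?)([^\"]*)\\1.*', "\\2", qual[[1]]) else
        sprintf("%s_%d", key, a)
    genes[[length(genes) + 1L]] <-
      data.frame(name = nm, start = a - 1, end = b, strand = strand,
                 stringsAsFactors = FALSE)
  }
  genes <- if (length(genes)) do.call(rbind, genes)
  # GenBank lists both a gene feature and its tRNA/rRNA child: deduplicate
  if (!is.null(genes))
    genes <- genes[!duplicated(genes[c("start", "end", "strand")]), ]
  mt_geometry(L, genes = genes, name = sub("\\.[^.]*$", "", basename(path)))
}

#' Merge promoter/factor/quadruplex annotation into a gene-only geometry
#'
#' GenBank and GFF3 input carry genes only; regulatory features are supplied
#' as a TSV overlay and merged with this helper.
#'
#' @param g an `mt_geometry` (typically genes only).
#' @param overlay an `mt_geometry` whose promoters, factor sites and
#'   quadruplex sites are copied onto `g`.
#' @return the merged `mt_geometry`.
#' @export
merge_geometry <- function(g, overlay) {
  stopifnot(inherits(g, "mt_geometry"), inherits(overlay, "mt_geometry"))
  if (g$length != overlay$length)
    stop("geometries have different lengths")
  g$promoters <- overlay$promoters
  g$factor_sites <- overlay$factor_sites
  g$quadruplex_sites <- overlay$quadruplex_sites
  validate_geometry(g)
}

#' Relative promoter intensities of the frog mitochondrial promoters
#'
#' The five frog promoters initiate at fixed intensities relative to LSP1:
#' HSP1 13.6%, HSP2 60.0%, LSP1 100%, LSP2A 16.6%, LSP2B 38.2%.
#'
#' @param lsp1_intensity LSP1 binding-attempt intensity (attempts/s), >= 0.
#' @return named numeric vector of intensities for all five promoters.
#' @export
frog_promoter_intensities <- function(lsp1_intensity) {
  if (!is.numeric(lsp1_intensity) || length(lsp1_intensity) != 1L ||
      is.na(lsp1_intensity) || lsp1_intensity < 0)
    stop("'lsp1_intensity' must be a single non-negative number")
  c(HSP1 = 0.136, HSP2 = 0.600, LSP1 = 1.000, LSP2A = 0.166,
    LSP2B = 0.382) * lsp1_intensity
}
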