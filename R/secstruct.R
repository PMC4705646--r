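## Secondary-structure parsing and topology decomposition.
##
## Input formats:
##  * dot-bracket with bracket levels () [] {} <> (all pairs canonical);
##  * pair-list TSV with columns i, j, class and optional `# numbering:` header;
##  * regions TSV with columns name, positions ("12-16,35-38" syntax).
## Positions are 1-based and inclusive throughout; files may instead use an
## external (crystal) numbering declared in a header line, which is kept as
## the numbering map.

.BRACKETS <- list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))

#' Construct or parse a secondary structure
#'
#' Accepts either a dot-bracket string (multi-level brackets for pseudoknots)
#' or an explicit pair table. Dot-bracket cannot express pair classes, so all
#' its pairs are canonical; noncanonical internal-loop pairs can only be
#' declared through the pair-table channel (or [readPairList()]).
#'
#' @param sequence residue letters as a single string or character vector.
#' @param dotbracket dot-bracket string, or `NULL` when `pairs` is given.
#' @param pairs data.frame with columns `i`, `j` and optionally `class`.
#' @param numbering optional integer vector of external residue numbers.
#' @return a [SecondaryStructure-class] object.
#' @examples
#' parseStructure("GGGAAACCC", "(((...)))")
#' @export
parseStructure <- function(sequence, dotbracket = NULL, pairs = NULL,
                           numbering = NULL) {
  seqv <- toupper(unlist(strsplit(paste(sequence, collapse = ""), "")))
  seqv[seqv == "T"] <- "U"
  n <- length(seqv)
  if (is.null(pairs)) {
    if (is.null(dotbracket)) stop("supply either dotbracket or pairs")
    pairs <- .parseDotBracket(dotbracket, n)
  } else {
    pairs <- as.data.frame(pairs)
    if (is.null(pairs$class)) pairs$class <- "canonical"
    bad <- !stats::complete.cases(pairs[c("i", "j")])
    if (any(bad)) stop("pair-list rows must have both i and j")
  }
  if (is.null(numbering)) numbering <- seq_len(n)
  pairs <- pairs[order(pairs$i), c("i", "j", "class"), drop = FALSE]
  rownames(pairs) <- NULL
  new("SecondaryStructure", sequence = seqv,
      pairs = data.frame(i = as.integer(pairs$i), j = as.integer(pairs$j),
                         class = as.character(pairs$class)),
      numbering = as.integer(numbering))
}

.parseDotBracket <- function(db, n) {
  ch <- unlist(strsplit(db, ""))
  if (length(ch) != n)
    stop(sprintf("dot-bracket length %d does not match sequence length %d",
                 length(ch), n))
  out <- list()
  for (lv in .BRACKETS) {
    stack <- integer()
    for (k in seq_along(ch)) {
      if (ch[k] == lv[1]) stack <- c(stack, k)
      else if (ch[k] == lv[2]) {
        if (!length(stack))
          stop(sprintf("unbalanced bracket '%s' at position %d", lv[2], k))
        out[[length(out) + 1L]] <- c(stack[length(stack)], k)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop(sprintf("unbalanced bracket '%s' at position %d", lv[1], stack[1]))
  }
  known <- c(".", "-", unlist(.BRACKETS))
  if (any(!ch %in% known))
    stop("unknown dot-bracket character: ", setdiff(ch, known)[1])
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), class = character()))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], class = "canonical")
}

#' Serialize a structure to dot-bracket
#'
#' Crossing pairs are pushed to higher bracket levels greedily. Noncanonical
#' pairs are dropped with a warning (dot-bracket cannot carry the class).
#' @param ss a [SecondaryStructure-class]
#' @return a dot-bracket string
#' @export
asDotBracket <- function(ss) {
  p <- ss@pairs
  if (any(p$class != "canonical"))
    warning("noncanonical pairs are not representable in dot-bracket; dropped")
  p <- p[p$class == "canonical", , drop = FALSE]
  ch <- rep(".", length(ss@sequence))
  lvl <- rep(NA_integer_, nrow(p))
  for (k in seq_len(nrow(p))) {
    used <- 1L
    repeat {
      prev <- which(lvl == used)
      cross <- any(.crosses(p$i[k], p$j[k], p$i[prev], p$j[prev]))
      if (!cross) break
      used <- used + 1L
      if (used > length(.BRACKETS)) stop("structure needs > 4 bracket levels")
    }
    lvl[k] <- used
  }
  for (k in seq_len(nrow(p))) {
    ch[p$i[k]] <- .BRACKETS[[lvl[k]]][1]
    ch[p$j[k]] <- .BRACKETS[[lvl[k]]][2]
  }
  paste(ch, collapse = "")
}

.crosses <- function(i, j, iv, jv) {
  (iv < i & i < jv & jv < j) | (i < iv & iv < j & j < jv)
}

#' Does the structure contain crossing (pseudoknotted) pairs?
#' @param ss a [SecondaryStructure-class]
#' @export
hasPseudoknot <- function(ss) {
  p <- ss@pairs
  if (nrow(p) < 2) return(FALSE)
  for (k in seq_len(nrow(p) - 1)) {
    idx <- (k + 1):nrow(p)
    if (any(.crosses(p$i[k], p$j[k], p$i[idx], p$j[idx]))) return(TRUE)
  }
  FALSE
}

#' Read a pair-list TSV
#'
#' Columns `i j class`; positions may be in an external numbering declared by
#' a header line `# numbering: <first> <last>`. A `# sequence:` header or a
#' companion `sequence` argument supplies residues.
#' @param file path to the TSV
#' @param sequence optional sequence overriding any header
#' @return [SecondaryStructure-class]
#' @export
readPairList <- function(file, sequence = NULL) {
  hdr <- .readHeaders(file)
  tab <- read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (is.null(sequence)) sequence <- hdr$sequence
  if (is.null(sequence)) stop("no sequence in header or argument")
  n <- nchar(paste(sequence, collapse = ""))
  numbering <- if (!is.null(hdr$numbering)) {
    seq(hdr$numbering[1], hdr$numbering[2])
  } else seq_len(n)
  if (length(numbering) != n) stop("numbering header does not span sequence")
  idx <- function(x) match(x, numbering)
  if (any(is.na(idx(tab$i))) || any(is.na(idx(tab$j))))
    stop("pair-list positions outside declared numbering")
  parseStructure(sequence,
                 pairs = data.frame(i = idx(tab$i), j = idx(tab$j),
                                    class = tab$class),
                 numbering = numbering)
}

#' Write the pair-list TSV for a structure (round-trips with [readPairList()])
#' @param ss [SecondaryStructure-class]; @param file output path
#' @export
writePairList <- function(ss, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# sequence: %s", paste(ss@sequence, collapse = "")), con)
  writeLines(sprintf("# numbering: %d %d", ss@numbering[1],
                     tail(ss@numbering, 1)), con)
  p <- ss@pairs
  p$i <- ss@numbering[p$i]; p$j <- ss@numbering[p$j]
  writeLines("i\tj\tclass", con)
  if (nrow(p))
    writeLines(sprintf("%d\t%d\t%s", p$i, p$j, p$class), con)
  invisible(file)
}

.readHeaders <- function(file) {
  lines <- readLines(file, n = 50)
  lines <- lines[startsWith(lines, "#")]
  out <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^#\\s*(\\w+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) {
      key <- m[2]; val <- trimws(m[3])
      out[[key]] <- if (key == "numbering") as.integer(strsplit(val, "\\s+")[[1]])
                    else val
    }
  }
  out
}

#' Read a regions TSV (columns `name`, `positions`)
#'
#' Positions use comma/range syntax in the file's declared numbering
#' (`# numbering:` header) or 1-based positions otherwise. For helices the
#' first range is taken as the reference strand for Euler frames.
#' @param file path; @param ss structure the regions refer to (for numbering)
#' @return named list of integer residue sets (1-based)
#' @export
readRegions <- function(file, ss = NULL) {
  hdr <- .readHeaders(file)
  tab <- read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  numbering <- if (!is.null(ss)) ss@numbering
               else if (!is.null(hdr$numbering)) seq(hdr$numbering[1], hdr$numbering[2])
               else NULL
  parseOne <- function(txt) {
    parts <- strsplit(txt, ",")[[1]]
    v <- unlist(lapply(parts, function(p) {
      r <- as.integer(strsplit(trimws(p), "-")[[1]])
      if (length(r) == 2) seq(r[1], r[2]) else r
    }))
    if (!is.null(numbering)) {
      i <- match(v, numbering)
      if (any(is.na(i))) stop("region position outside numbering: ", txt)
      i
    } else v
  }
  out <- lapply(tab$positions, parseOne)
  names(out) <- tab$name
  out
}

## ---- topology decomposition --------------------------------------------

#' Decompose a structure into its helix/linker topology graph
#'
#' Helices are maximal stacks of consecutive canonical pairs; noncanonical
#' pairs never join a rigid helix (they stay flexible in the chain model).
#' Maximal unpaired runs (including noncanonically paired residues) become
#' linker units. The unit adjacency graph connects chain neighbours and is
#' the substrate for [linkerClass()] and [countFlexiblePivots()].
#'
#' @param ss [SecondaryStructure-class]
#' @param regions optional named list from [readRegions()]; helix units whose
#'   strand ranges exactly match a region named `P*` inherit that name.
#' @return [TopologyGraph-class]
#' @export
decomposeTopology <- function(ss, regions = list()) {
  p <- ss@pairs[ss@pairs$class == "canonical", , drop = FALSE]
  n <- length(ss@sequence)
  helices <- .maximalLadders(p)
  if (nrow(helices)) {
    helices$name <- paste0("H", seq_len(nrow(helices)))
    ## inherit names from regions that exactly cover the helix strands
    for (nm in names(regions)) {
      rset <- sort(regions[[nm]])
      for (h in seq_len(nrow(helices))) {
        hset <- sort(c(seq(helices$s1_start[h], helices$s1_end[h]),
                       seq(helices$s2_start[h], helices$s2_end[h])))
        if (identical(rset, hset)) helices$name[h] <- nm
      }
    }
  }
  paired <- logical(n)
  if (nrow(helices))
    for (h in seq_len(nrow(helices)))
      paired[c(seq(helices$s1_start[h], helices$s1_end[h]),
               seq(helices$s2_start[h], helices$s2_end[h]))] <- TRUE

  ## units: helix strands are part of their helix unit; contiguous unpaired
  ## runs are linker units
  unitOf <- integer(n)
  units <- list()
  uid <- 0L
  r <- 1L
  strandUnit <- integer(0)
  helixUnit <- rep(NA_integer_, nrow(helices))
  while (r <= n) {
    if (paired[r]) {
      h <- which((helices$s1_start <= r & r <= helices$s1_end) |
                 (helices$s2_start <= r & r <= helices$s2_end))[1]
      if (is.na(helixUnit[h])) {
        uid <- uid + 1L
        helixUnit[h] <- uid
        units[[uid]] <- list(id = uid, kind = "helix",
                             first = helices$s1_start[h],
                             last = helices$s2_end[h], helix = h,
                             n_res = 2L * helices$n_bp[h])
      }
      u <- helixUnit[h]
      end <- if (r <= helices$s1_end[h]) helices$s1_end[h] else helices$s2_end[h]
      unitOf[r:end] <- u
      r <- end + 1L
    } else {
      end <- r
      while (end < n && !paired[end + 1L]) end <- end + 1L
      uid <- uid + 1L
      units[[uid]] <- list(id = uid, kind = "linker", first = r, last = end,
                           helix = NA_integer_, n_res = end - r + 1L)
      unitOf[r:end] <- uid
      r <- end + 1L
    }
  }
  units <- do.call(rbind, lapply(units, as.data.frame))
  if (is.null(units)) units <- data.frame(id = integer(), kind = character(),
                                          first = integer(), last = integer(),
                                          helix = integer(), n_res = integer())
  ## adjacency: chain neighbours with different units
  edges <- data.frame(from = integer(), to = integer(), nt = integer())
  if (n > 1) {
    brk <- which(unitOf[-n] != unitOf[-1])
    e <- unique(data.frame(from = unitOf[brk], to = unitOf[brk + 1L]))
    ## nt of an edge: size of the linker unit involved (0 for helix-helix)
    e$nt <- ifelse(units$kind[e$from] == "linker", units$n_res[e$from],
                   ifelse(units$kind[e$to] == "linker", units$n_res[e$to], 0L))
    edges <- e
  }
  new("TopologyGraph", ss = ss, helices = helices, units = units,
      unitOf = as.integer(unitOf), edges = edges, regions = regions)
}

.maximalLadders <- function(p) {
  if (!nrow(p))
    return(data.frame(name = character(), s1_start = integer(),
                      s1_end = integer(), s2_start = integer(),
                      s2_end = integer(), n_bp = integer()))
  p <- p[order(p$i), ]
  key <- paste(p$i, p$j)
  isStart <- !(paste(p$i - 1L, p$j + 1L) %in% key)
  out <- list()
  for (s in which(isStart)) {
    i <- p$i[s]; j <- p$j[s]; len <- 1L
    while (paste(i + len, j - len) %in% key) len <- len + 1L
    out[[length(out) + 1L]] <- data.frame(
      s1_start = i, s1_end = i + len - 1L,
      s2_start = j - len + 1L, s2_end = j, n_bp = len)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$s1_start), ]
  rownames(out) <- NULL
  cbind(name = paste0("H", seq_len(nrow(out))), out)
}

.helixIndex <- function(tg, name) {
  h <- match(name, tg@helices$name)
  if (is.na(h)) stop("unknown helix: ", name)
  h
}

.helixPairs <- function(tg, h) {
  hh <- tg@helices[h, ]
  data.frame(i = seq(hh$s1_start, hh$s1_end),
             j = seq(hh$s2_end, hh$s2_start))
}

#' Classify how two helices are linked
#'
#' Categories: `pseudoknot` when any pairs of the two helices cross;
#' `two_way` when the helices are joined on both strands through unpaired
#' linkers (or directly bonded) with no other helix between; `single_linker`
#' when the helices are joined by exactly one single-stranded linker of at
#' most 3 nt (the peripheral-attachment pattern of apical arms);
#' `indirect` otherwise.
#'
#' @param tg [TopologyGraph-class]; @param helixA,helixB helix names
#' @return character scalar
#' @export
linkerClass <- function(tg, helixA, helixB) {
  ha <- .helixIndex(tg, helixA); hb <- .helixIndex(tg, helixB)
  pa <- .helixPairs(tg, ha); pb <- .helixPairs(tg, hb)
  for (k in seq_len(nrow(pa)))
    if (any(.crosses(pa$i[k], pa$j[k], pb$i, pb$j))) return("pseudoknot")
  ua <- tg@units$id[which(tg@units$helix == ha)]
  ub <- tg@units$id[which(tg@units$helix == hb)]
  ## direct connections: chain paths between the two helix units passing only
  ## through linker units
  g <- igraph::graph_from_data_frame(tg@edges[c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = tg@units$id))
  other <- tg@units$id[tg@units$kind == "helix" & !tg@units$id %in% c(ua, ub)]
  g2 <- igraph::delete_vertices(g, as.character(other))
  paths <- igraph::all_simple_paths(g2, from = as.character(ua),
                                    to = as.character(ub))
  if (!length(paths)) return("indirect")
  linkNt <- vapply(paths, function(pp) {
    ids <- as.integer(names(pp))
    mid <- ids[!(ids %in% c(ua, ub))]
    sum(tg@units$n_res[match(mid, tg@units$id)])
  }, numeric(1))
  if (length(paths) >= 2 || any(linkNt == 0)) return("two_way")
  if (min(linkNt) <= 3) return("single_linker")
  "indirect"
}

#' Count flexible pivots between two regions
#'
#' Counts the flexible articulation points on the shortest secondary-structure
#' path between two regions, treating helices as rigid segments. Each
#' flexible linker unit traversed contributes `ceiling(L/2)` pivots (L = its
#' single-stranded length); a direct helix-helix junction contributes 1; the
#' units containing the query regions themselves contribute 0.
#'
#' @param tg [TopologyGraph-class]
#' @param regionA,regionB region names (must exist in `tg@regions`)
#' @return integer pivot count
#' @export
countFlexiblePivots <- function(tg, regionA, regionB) {
  for (r in c(regionA, regionB))
    if (!r %in% names(tg@regions)) stop("unknown region: ", r)
  unitsA <- unique(tg@unitOf[tg@regions[[regionA]]])
  unitsB <- unique(tg@unitOf[tg@regions[[regionB]]])
  ## node weights: cost of *traversing* a unit
  w <- ifelse(tg@units$kind == "linker", ceiling(tg@units$n_res / 2), 0)
  w[tg@units$id %in% c(unitsA, unitsB)] <- 0
  ## edge weight: traversal cost of the target unit; direct helix-helix
  ## junctions (0-nt) cost 1
  e <- tg@edges
  ew <- w[e$to] + ifelse(e$nt == 0, 1, 0)
  ## symmetric graph: add reverse edges with matching weights
  e2 <- data.frame(from = c(e$from, e$to), to = c(e$to, e$from))
  ew2 <- c(ew, w[e$from] + ifelse(e$nt == 0, 1, 0))
  g <- igraph::graph_from_data_frame(e2, directed = TRUE,
                                     vertices = data.frame(name = tg@units$id))
  d <- igraph::distances(g, v = as.character(unitsA),
                         to = as.character(unitsB), mode = "out",
                         weights = ew2)
  as.integer(min(d))
}

#' Named regions attached to a topology graph
#' @param tg [TopologyGraph-class]
#' @export
regions <- function(tg) tg@regions

#' Helix table of a topology graph
#' @param tg [TopologyGraph-class]
#' @export
helices <- function(tg) tg@helices

#' Sequence accessor
#' @param ss [SecondaryStructure-class]
#' @export
residues <- function(ss) ss@sequence

#' Pair table accessor
#' @param ss [SecondaryStructure-class]
#' @export
pairTable <- function(ss) ss@pairs

#' Resolve an external residue label ("A39" or "39") to a 1-based position
#' @param ss [SecondaryStructure-class]; @param label character or integer
#' @export
resolveResidue <- function(ss, label) {
  num <- suppressWarnings(as.integer(gsub("^[ACGUN]", "", as.character(label))))
  pos <- match(num, ss@numbering)
  if (any(is.na(pos))) stop("residue not in numbering map: ",
                            paste(label[is.na(pos)], collapse = ", "))
  letter <- gsub("[0-9]+$", "", as.character(label))
  has <- nzchar(letter)
  if (any(has) && any(ss@sequence[pos[has]] != letter[has]))
    warning("residue letter mismatch against sequence for: ",
            paste(label[has][ss@sequence[pos[has]] != letter[has]], collapse = ", "))
  pos
}
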