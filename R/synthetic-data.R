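# Synthetic genomes, isoform sets, and paired-end reads with machine-readable
# truth, emulating a large-insert Illumina library over a plant mitogenome:
# ~365 kb scaffolds, 2 x 125 bp mates from an ~800 bp insert library at
# ~28-35x depth, planted dispersed repeats (<= ~500 bp), planted
# plastid-derived segments (1-2 kb), and multi-isoform topologies.

#' Specify a synthetic genome with planted features
#'
#' Describes a random scaffold plus optional planted dispersed repeats and
#' plastid-derived segments (MIPTs). Repeats are copies of an internal source
#' interval mutated to a requested identity and written elsewhere in the
#' scaffold (replacement, so the total length is unchanged); MIPTs copy a
#' donor interval from a companion plastome-like sequence into the scaffold
#' the same way. All coordinates are 1-based, fully closed.
#'
#' @param length Scaffold length in bases (> 0).
#' @param gc GC fraction in \[0, 1\].
#' @param repeats Optional tibble with columns `length`, `identity`,
#'   `source_start`, `copy_start`, and optionally `inverted` (logical,
#'   default `FALSE`): each row plants one repeat pair.
#' @param mipts Optional tibble with columns `donor_start`, `donor_end`
#'   (interval on the plastome), `insert_start` (scaffold position), and
#'   `identity`.
#' @param plastome_length Length of the companion plastome-like sequence.
#' @param seed Integer seed; identical specs and seeds yield byte-identical
#'   sequences.
#' @return An object of class `genome_spec`.
#' @seealso [generate_genome()]
#' @export
genome_spec <- function(length, gc = 0.44, repeats = NULL, mipts = NULL,
                        plastome_length = 30000L, seed = 1L) {
  stopifnot(length > 0, gc >= 0, gc <= 1, plastome_length >= 0)
  repeats <- normalise_repeats(repeats, length)
  mipts <- normalise_mipts(mipts, length, plastome_length)
  check_planted_overlap(repeats, mipts)
  structure(
    list(
      length = as.integer(length), gc = gc, repeats = repeats, mipts = mipts,
      plastome_length = as.integer(plastome_length), seed = as.integer(seed)
    ),
    class = "genome_spec"
  )
}

normalise_repeats <- function(repeats, genome_length) {
  if (is.null(repeats) || nrow(repeats) == 0L) {
    return(tibble(
      length = integer(), identity = double(), source_start = integer(),
      copy_start = integer(), inverted = logical()
    ))
  }
  stopifnot(all(c("length", "identity", "source_start", "copy_start") %in% names(repeats)))
  repeats <- as_tibble(repeats)
  if (!"inverted" %in% names(repeats)) repeats$inverted <- FALSE
  ends <- c(repeats$source_start + repeats$length - 1L,
            repeats$copy_start + repeats$length - 1L)
  if (any(repeats$length <= 0L)) abort("planted repeat length must be positive")
  if (any(c(repeats$source_start, repeats$copy_start) < 1L) || any(ends > genome_length)) {
    abort("planted repeat interval falls outside [1, length]")
  }
  if (any(repeats$identity < 0 | repeats$identity > 1)) {
    abort("repeat identity must lie in [0, 1]")
  }
  repeats
}

normalise_mipts <- function(mipts, genome_length, plastome_length) {
  if (is.null(mipts) || nrow(mipts) == 0L) {
    return(tibble(
      donor_start = integer(), donor_end = integer(),
      insert_start = integer(), identity = double()
    ))
  }
  stopifnot(all(c("donor_start", "donor_end", "insert_start", "identity") %in% names(mipts)))
  mipts <- as_tibble(mipts)
  len <- mipts$donor_end - mipts$donor_start + 1L
  if (any(len <= 0L)) abort("MIPT donor interval must have positive length")
  if (any(mipts$donor_start < 1L) || any(mipts$donor_end > plastome_length)) {
    abort("MIPT donor interval falls outside the plastome")
  }
  if (any(mipts$insert_start < 1L) || any(mipts$insert_start + len - 1L > genome_length)) {
    abort("MIPT insertion interval falls outside [1, length]")
  }
  mipts
}

# Planted (written) intervals on the scaffold must not overlap one another.
check_planted_overlap <- function(repeats, mipts) {
  iv <- rbind(
    if (nrow(repeats)) cbind(repeats$source_start, repeats$source_start + repeats$length - 1L),
    if (nrow(repeats)) cbind(repeats$copy_start, repeats$copy_start + repeats$length - 1L),
    if (nrow(mipts)) cbind(mipts$insert_start,
                           mipts$insert_start + (mipts$donor_end - mipts$donor_start))
  )
  if (is.null(iv) || nrow(iv) < 2L) return(invisible(TRUE))
  ord <- order(iv[, 1])
  iv <- iv[ord, , drop = FALSE]
  clash <- which(iv[-1, 1] <= iv[-nrow(iv), 2])
  if (length(clash)) {
    abort(sprintf(
      "planted intervals overlap: [%d, %d] and [%d, %d]",
      iv[clash[1], 1], iv[clash[1], 2], iv[clash[1] + 1, 1], iv[clash[1] + 1, 2]
    ))
  }
  invisible(TRUE)
}

#' Generate a synthetic genome and feature truth table
#'
#' Realizes a [genome_spec()]: draws the scaffold and plastome, plants the
#' requested repeats and MIPTs, and returns the sequences together with a
#' truth table describing every planted feature. Deterministic given the
#' spec's seed.
#'
#' @param spec A [genome_spec()].
#' @return A list of class `synthetic_genome` with elements `genome`
#'   (character scalar), `plastome` (character scalar), and `features`, a
#'   tibble with one row per planted feature: `type` ("repeat" or "mipt"),
#'   `start`, `end`, `length`, `identity`, `partner_start`, `partner_end`
#'   (the source interval on the scaffold for repeats, the donor interval on
#'   the plastome for MIPTs) and `inverted`.
#' @export
#' @examples
#' g <- generate_genome(genome_spec(10000, seed = 7))
#' nchar(g$genome)
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, {
    genome <- random_dna(spec$length, spec$gc)
    plastome <- random_dna(spec$plastome_length, spec$gc)
    feats <- list()
    for (i in seq_len(nrow(spec$repeats))) {
      r <- spec$repeats[i, ]
      src <- substr(genome, r$source_start, r$source_start + r$length - 1L)
      copy <- mutate_to_identity(src, r$identity)
      if (isTRUE(r$inverted)) copy <- revcomp(copy)
      substr(genome, r$copy_start, r$copy_start + r$length - 1L) <- copy
      feats[[length(feats) + 1L]] <- tibble(
        type = "repeat",
        start = as.integer(r$copy_start), end = as.integer(r$copy_start + r$length - 1L),
        length = as.integer(r$length), identity = r$identity,
        partner_start = as.integer(r$source_start),
        partner_end = as.integer(r$source_start + r$length - 1L),
        inverted = isTRUE(r$inverted)
      )
    }
    for (i in seq_len(nrow(spec$mipts))) {
      m <- spec$mipts[i, ]
      len <- m$donor_end - m$donor_start + 1L
      seg <- mutate_to_identity(substr(plastome, m$donor_start, m$donor_end), m$identity)
      substr(genome, m$insert_start, m$insert_start + len - 1L) <- seg
      feats[[length(feats) + 1L]] <- tibble(
        type = "mipt",
        start = as.integer(m$insert_start), end = as.integer(m$insert_start + len - 1L),
        length = as.integer(len), identity = m$identity,
        partner_start = as.integer(m$donor_start), partner_end = as.integer(m$donor_end),
        inverted = FALSE
      )
    }
    features <- if (length(feats)) bind_rows(feats) else tibble(
      type = character(), start = integer(), end = integer(), length = integer(),
      identity = double(), partner_start = integer(), partner_end = integer(),
      inverted = logical()
    )
    structure(
      list(genome = genome, plastome = plastome, features = features, spec = spec),
      class = "synthetic_genome"
    )
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_genome> %s bp scaffold, %s bp plastome, %d planted feature(s)\n",
    format(nchar(x$genome), big.mark = ","),
    format(nchar(x$plastome), big.mark = ","), nrow(x$features)
  ))
  invisible(x)
}

#' Specify a paired-end sequencing library
#'
#' Defaults emulate a 2 x 125 bp library with an ~800 bp insert at 30-fold
#' depth. Insert lengths are drawn from a Normal truncated to
#' \[2 x read_length, molecule length\].
#'
#' @param insert_mean Mean insert (fragment) length in bases.
#' @param insert_sd Insert-length standard deviation in bases.
#' @param read_length Mate length in bases.
#' @param depth Target fold-coverage of a full-stoichiometry molecule.
#' @param error_rate Per-base substitution probability in \[0, 0.1).
#' @param seed Integer seed.
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(insert_mean = 800L, insert_sd = 80L, read_length = 125L,
                         depth = 30, error_rate = 0, seed = 1L) {
  stopifnot(
    read_length <= insert_mean, depth > 0, insert_sd >= 0,
    error_rate >= 0, error_rate < 0.1, read_length > 0
  )
  structure(
    list(
      insert_mean = insert_mean, insert_sd = insert_sd,
      read_length = as.integer(read_length), depth = depth,
      error_rate = error_rate, seed = as.integer(seed)
    ),
    class = "library_spec"
  )
}

#' Build molecule sequences from an isoform specification
#'
#' An isoform specification lists, for each molecule, an ordered set of
#' oriented scaffold intervals; the molecule sequence is the concatenation of
#' the (oriented) segment sequences. Circular molecules are flagged so that
#' read sampling wraps the origin. Copy numbers are relative: read sampling
#' normalizes them so the highest-copy molecule attains the target depth.
#'
#' @param genome A scaffold sequence (character scalar) or a
#'   [generate_genome()] result.
#' @param isoforms Tibble with one row per segment, columns `molecule`
#'   (identifier), `start`, `end`, optionally `strand` ("+"/"-", default "+"),
#'   `topology` ("circular"/"linear") and `copy_number` (constant within a
#'   molecule). Segment order within a molecule follows row order.
#' @return Tibble with one row per molecule: `molecule`, `topology`,
#'   `copy_number`, `length`, `seq`.
#' @export
#' @examples
#' g <- generate_genome(genome_spec(5000, seed = 1))
#' iso <- tibble::tibble(
#'   molecule = "m1", start = 1, end = 5000,
#'   topology = "circular", copy_number = 1
#' )
#' build_isoforms(g, iso)
build_isoforms <- function(genome, isoforms) {
  if (inherits(genome, "synthetic_genome")) genome <- genome$genome
  stopifnot(is.character(genome), length(genome) == 1L)
  iso <- as_tibble(isoforms)
  stopifnot(all(c("molecule", "start", "end") %in% names(iso)))
  if (!"strand" %in% names(iso)) iso$strand <- "+"
  if (!"topology" %in% names(iso)) iso$topology <- "linear"
  if (!"copy_number" %in% names(iso)) iso$copy_number <- 1
  L <- nchar(genome)
  if (any(iso$end < iso$start)) abort("zero- or negative-length segment in isoform spec")
  if (any(iso$start < 1L) || any(iso$end > L)) {
    abort("isoform segment falls outside the scaffold")
  }
  if (any(iso$copy_number <= 0)) abort("copy_number must be positive")

  cov <- logical(L)
  for (i in seq_len(nrow(iso))) cov[iso$start[i]:iso$end[i]] <- TRUE
  if (!all(cov)) {
    warn(sprintf(
      "%d scaffold base(s) are covered by no molecule", sum(!cov)
    ))
  }

  iso %>%
    mutate(.row = row_number()) %>%
    group_by(.data$molecule) %>%
    summarise(
      topology = first(.data$topology),
      copy_number = first(.data$copy_number),
      seq = paste(
        ifelse(.data$strand == "-",
          revcomp(substring(genome, .data$start, .data$end)),
          substring(genome, .data$start, .data$end)
        )[order(.data$.row)],
        collapse = ""
      ),
      .groups = "drop"
    ) %>%
    mutate(length = nchar(.data$seq)) %>%
    select("molecule", "topology", "copy_number", "length", "seq")
}

#' Canonical two-circle-plus-bridge isoform specification
#'
#' Convenience constructor for the multi-isoform condition in which a linear
#' scaffold decomposes into a left circle (everything before a low-copy
#' internal segment, circularized), a right circle (everything after it,
#' circularized), and the internal segment itself as a linear bridge at
#' reduced copy number. Reads simulated from these molecules reproduce the
#' diagnostic pattern: a coverage dip over the bridge and inconsistent-pair
#' clusters joining each scaffold end to the near flank of the dip.
#'
#' @param scaffold_length Scaffold length in bases.
#' @param bridge_start,bridge_end 1-based closed bounds of the bridge segment.
#' @param circle_copy,bridge_copy Relative copy numbers (ratio is what
#'   matters; default 3:1).
#' @param bridge_pad Bases of flanking scaffold carried by the bridge
#'   molecule on each side (clamped to the scaffold). The low-copy molecule
#'   is a fragment of the linearized full-genome form, so it extends past
#'   the bridge proper; the padding keeps paired-read sampling edge effects
#'   out of the bridge interval. Coverage over the pad is `circle_copy +
#'   bridge_copy`, a relative excess too small to register as a spike.
#' @return An isoform tibble suitable for [build_isoforms()].
#' @export
two_circle_bridge_spec <- function(scaffold_length, bridge_start, bridge_end,
                                   circle_copy = 3, bridge_copy = 1,
                                   bridge_pad = 1100L) {
  stopifnot(
    bridge_start > 1, bridge_end < scaffold_length, bridge_start <= bridge_end
  )
  tibble(
    molecule = c("circle_left", "circle_right", "bridge"),
    start = c(1L, bridge_end + 1L, max(1L, bridge_start - bridge_pad)),
    end = c(bridge_start - 1L, scaffold_length,
            min(scaffold_length, bridge_end + bridge_pad)),
    strand = "+",
    topology = c("circular", "circular", "linear"),
    copy_number = c(circle_copy, circle_copy, bridge_copy)
  )
}

#' Simulate paired-end reads from a set of molecules
#'
#' Draws inserts with truncated-Normal lengths, inward-facing mates, molecule
#' choice proportional to copy_number x length (copy numbers normalized so
#' the maximum is 1, which pins the highest-copy molecule at the target
#' depth), and origin wrap-around on circular molecules. Every pair is logged
#' in a truth table.
#'
#' @param molecules Tibble from [build_isoforms()] (columns `molecule`,
#'   `topology`, `copy_number`, `length`, `seq`).
#' @param lib A [library_spec()].
#' @return A list of class `read_simulation`: `reads` (tibble `read_id`,
#'   `mate`, `seq`, `qual`) and `truth` (tibble `read_id`, `molecule`,
#'   `start`, `insert_length`, `flipped`).
#' @export
simulate_pairs <- function(molecules, lib) {
  stopifnot(inherits(lib, "library_spec"))
  mol <- as_tibble(molecules)
  stopifnot(all(c("molecule", "topology", "copy_number", "length", "seq") %in% names(mol)))
  rl <- lib$read_length
  if (any(mol$length < 2L * rl)) {
    abort("molecule shorter than two read lengths cannot be sequenced")
  }
  short <- mol$topology != "circular" & mol$length < lib$insert_mean + 3 * lib$insert_sd
  if (any(short)) {
    abort(sprintf(
      "linear molecule '%s' is shorter than insert_mean + 3*insert_sd",
      mol$molecule[which(short)[1]]
    ))
  }

  withr::with_seed(lib$seed, {
    cn <- mol$copy_number / max(mol$copy_number)
    # molecule weight uses the number of positions an insert can occupy:
    # full length for circles, length - insert_mean + 1 for linear
    # molecules. Weighting by raw length would over-cover the interior of
    # short linear molecules, whose inserts are squeezed away from the ends.
    len_eff <- ifelse(mol$topology == "circular", mol$length,
      pmax(mol$length - lib$insert_mean + 1, 1)
    )
    total_bases <- lib$depth * sum(len_eff * cn)
    n_pairs <- max(1L, round(total_bases / (2 * rl)))
    widx <- sample.int(nrow(mol), n_pairs, replace = TRUE, prob = cn * len_eff)

    ins <- round(rnorm(n_pairs, lib$insert_mean, lib$insert_sd))
    lo <- 2L * rl
    hi <- mol$length[widx]
    bad <- which(ins < lo | ins > hi)
    while (length(bad)) {
      ins[bad] <- round(rnorm(length(bad), lib$insert_mean, lib$insert_sd))
      bad <- which(ins < lo | ins > hi)
    }

    circ <- mol$topology[widx] == "circular"
    start <- integer(n_pairs)
    start[circ] <- sample.int(.Machine$integer.max, sum(circ), replace = TRUE) %%
      mol$length[widx][circ] + 1L
    if (any(!circ)) {
      span <- mol$length[widx][!circ] - ins[!circ] + 1L
      start[!circ] <- floor(runif(sum(!circ)) * span) + 1L
    }

    # doubled sequence gives wrap-around substrings for circular molecules
    dbl <- ifelse(mol$topology == "circular", paste0(mol$seq, mol$seq), mol$seq)
    insert_seq <- substring(dbl[widx], start, start + ins - 1L)
    m1 <- substring(insert_seq, 1L, rl)
    m2 <- revcomp(substring(insert_seq, ins - rl + 1L, ins))
    flipped <- runif(n_pairs) < 0.5
    tmp <- m1[flipped]
    m1[flipped] <- m2[flipped]
    m2[flipped] <- tmp

    m1 <- add_read_errors(m1, lib$error_rate)
    m2 <- add_read_errors(m2, lib$error_rate)

    ids <- sprintf("sim_%06d", seq_len(n_pairs))
    reads <- tibble(
      read_id = rep(ids, 2L),
      mate = rep(1:2, each = n_pairs),
      seq = c(m1, m2),
      qual = strrep("I", rl)
    )
    truth <- tibble(
      read_id = ids, molecule = mol$molecule[widx],
      start = start, insert_length = as.integer(ins), flipped = flipped
    )
    structure(list(reads = reads, truth = truth, library = lib),
      class = "read_simulation"
    )
  })
}

#' @export
print.read_simulation <- function(x, ...) {
  cat(sprintf(
    "<read_simulation> %s read pairs (2 x %d bp, insert %g +/- %g bp)\n",
    format(nrow(x$truth), big.mark = ","), x$library$read_length,
    x$library$insert_mean, x$library$insert_sd
  ))
  invisible(x)
}

#' Write simulation truth tables
#'
#' @param x A `read_simulation` or `synthetic_genome`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(x, path) {
  tab <- if (inherits(x, "read_simulation")) x$truth
  else if (inherits(x, "synthetic_genome")) x$features
  else abort("x must be a read_simulation or synthetic_genome")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
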