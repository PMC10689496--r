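#' Simulate a dated language tree
#'
#' Runs a forward birth-death process (rates per year) from a single lineage
#' until the configured number of living lineages is reached; that moment is
#' the present (age 0 BP). Extinct side branches are pruned. Optionally one
#' additional "historically attested" tip is grafted at
#' `cfg$tree$extinct_tip_age` years BP, attached uniformly over the tree
#' length older than that age — the shape a fossilized birth-death tree prior
#' expects from a family with one non-surviving, dated language.
#'
#' @param cfg a [sim_config()]
#' @return An `ape::phylo` tree whose tips sit at their sampling ages
#'   (extant tips at 0 BP).
#' @export
simulate_dated_tree <- function(cfg) {
  tc <- cfg$tree
  if (tc$birth_rate <= 0) stop("birth_rate must be positive", call. = FALSE)
  set.seed(derive_seed(cfg$seed, "tree"))
  for (attempt in 1:200) {
    phy <- sim_bd_forward(tc$n_extant_tips, tc$birth_rate, tc$death_rate)
    if (is.null(phy)) next
    if (is.null(tc$extinct_tip_age)) return(phy)
    root_age <- max(ape::node.depth.edgelength(phy))
    if (root_age <= tc$extinct_tip_age) next  # fossil must attach below the root
    return(graft_dated_tip(phy, "fossil", tc$extinct_tip_age))
  }
  stop("failed to simulate a tree compatible with extinct_tip_age ",
       "after 200 attempts", call. = FALSE)
}

# forward birth-death until `n` lineages are alive; returns pruned phylo
# (extant tips only) or NULL if the process died out
sim_bd_forward <- function(n, birth, death) {
  for (attempt in 1:1000) {
    parent <- c(NA_integer_)
    t_birth <- c(0)
    t_end <- c(NA_real_)
    active <- 1L
    t <- 0
    failed <- FALSE
    while (length(active) < n) {
      k <- length(active)
      t <- t + stats::rexp(1, k * (birth + death))
      i <- active[sample.int(k, 1)]
      if (stats::runif(1) < birth / (birth + death)) {
        id <- length(parent) + 1:2
        parent <- c(parent, i, i)
        t_birth <- c(t_birth, t, t)
        t_end <- c(t_end, NA, NA)
        t_end[i] <- t
        active <- c(setdiff(active, i), id)
      } else {
        t_end[i] <- t
        active <- setdiff(active, i)
        if (!length(active)) { failed <- TRUE; break }
      }
    }
    if (failed) next
    # observe the standing flora of n lineages at a memoryless instant before
    # the next event, so the youngest split sits strictly above the present
    present <- t + stats::rexp(1, n * (birth + death))
    t_end[active] <- present
    kids <- split(seq_along(parent), factor(parent, seq_along(parent)))
    is_extant <- seq_along(parent) %in% active
    desc <- function(id) {
      ks <- kids[[id]]
      if (!length(ks)) {
        if (!is_extant[id]) return(NULL)
        return(list(str = sprintf("t%d", id), time = present))
      }
      subs <- Filter(Negate(is.null), lapply(ks, desc))
      if (!length(subs)) return(NULL)
      if (length(subs) == 1) return(subs[[1]])
      list(
        str = sprintf("(%s:%.10g,%s:%.10g)",
                      subs[[1]]$str, subs[[1]]$time - t_end[id],
                      subs[[2]]$str, subs[[2]]$time - t_end[id]),
        time = t_end[id]
      )
    }
    top <- desc(1L)
    phy <- ape::read.tree(text = paste0(top$str, ";"))
    phy$tip.label <- paste0("L", seq_len(n))
    return(phy)
  }
  NULL
}

#' Graft a dated tip onto a tree
#'
#' Attaches a new tip at `tip_age` years BP, with the attachment point drawn
#' uniformly over the parts of existing branches older than `tip_age`.
#'
#' @param phy dated `phylo` (extant tips at age 0)
#' @param label new tip label
#' @param tip_age age of the new tip, years BP
#' @param sister optional tip label: attach on that tip's pendant branch
#'   (e.g. a historically attested ancestor variety attached to its modern
#'   continuation); by default the branch is drawn uniformly over tree length
#'   older than `tip_age`.
#' @return The enlarged `phylo`.
#' @export
graft_dated_tip <- function(phy, label, tip_age, sister = NULL) {
  depth <- ape::node.depth.edgelength(phy)
  root_age <- max(depth[seq_len(ape::Ntip(phy))])
  age <- root_age - depth  # age of each node/tip
  e <- phy$edge
  top_age <- age[e[, 1]]
  bot_age <- age[e[, 2]]
  overlap <- pmax(0, top_age - pmax(bot_age, tip_age))
  if (!is.null(sister)) {
    keep <- e[, 2] == match(sister, phy$tip.label)
    overlap[!keep] <- 0
  }
  if (all(overlap == 0)) stop("no eligible branch older than tip_age",
                              call. = FALSE)
  edge_i <- sample.int(nrow(e), 1, prob = overlap)
  attach_age <- stats::runif(1, pmax(bot_age[edge_i], tip_age), top_age[edge_i])
  tip <- structure(list(
    edge = matrix(c(2L, 1L), 1, 2),
    tip.label = label,
    edge.length = attach_age - tip_age,
    Nnode = 1L
  ), class = "phylo")
  out <- ape::bind.tree(phy, tip, where = e[edge_i, 2],
                        position = attach_age - bot_age[edge_i])
  ape::reorder.phylo(out, "cladewise")
}

#' Node and tip ages of a dated tree
#'
#' @param phy a `phylo` with branch lengths in years, at least one tip extant
#'   (or `tip_dates` supplied)
#' @param tip_dates optional named vector of tip sampling ages (years BP);
#'   defaults to the deepest tip being at 0 BP.
#' @return numeric vector of ages (years BP) indexed like ape's node numbers
#'   (tips first, then internal nodes).
#' @export
node_ages <- function(phy, tip_dates = NULL) {
  depth <- ape::node.depth.edgelength(phy)
  ntip <- ape::Ntip(phy)
  if (is.null(tip_dates)) {
    offset <- max(depth[seq_len(ntip)])
  } else {
    offset <- max(depth[seq_len(ntip)] + tip_dates[phy$tip.label])
  }
  offset - depth
}

#' Reference dated tree for the South Caucasian family
#'
#' Builds the five-tip dated tree used as simulation truth throughout the
#' package: Svan sister to the rest, Georgian and Zan diverging at
#' `karto_zan_age`, Zan splitting into Megrelian and Laz at `zan_age`, and
#' Old Georgian attached to the Georgian lineage as a dated tip at
#' `old_georgian_age` (its attachment height drawn uniformly above that age).
#'
#' @param root_age Svan / Karto-Zan split, years BP
#' @param karto_zan_age Georgian / Zan split, years BP
#' @param zan_age Megrelian / Laz split, years BP
#' @param old_georgian_age Old Georgian tip date, years BP
#' @param seed seed for the attachment height
#' @return a dated `phylo` with five tips.
#' @export
kartvelian_reference_tree <- function(root_age = 7641, karto_zan_age = 2617,
                                      zan_age = 1200, old_georgian_age = 900,
                                      seed = 1L) {
  txt <- sprintf(
    "((Georgian:%g,(Megrelian:%g,Laz:%g):%g):%g,Svan:%g);",
    karto_zan_age, zan_age, zan_age, karto_zan_age - zan_age,
    root_age - karto_zan_age, root_age
  )
  phy <- ape::read.tree(text = txt)
  set.seed(seed)
  graft_dated_tip(phy, "OldGeorgian", old_georgian_age, sister = "Georgian")
}
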