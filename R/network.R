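#' Build the observer-identifier network of an event
#'
#' Constructs the bipartite-style network linking the people who made
#' observations during an event to the people who identified those records
#' on the platform. Nodes are users with a role — `observer` (made event
#' records only), `identifier` (identified event records without attending),
#' or `both` — and an edge `(observer, identifier)` carries as weight the
#' number of identifications that identifier made on that observer's event
#' records. Identifier-only nodes are exactly the event's additional online
#' community: people engaged through identification without being present.
#'
#' Self-identifications (a participant identifying their own record) count
#' by default — without them no `both` role could arise from one's own
#' records — and can be excluded to study purely external engagement.
#' Identifications that reference no observation in `event_obs` are excluded
#' and reported in the `excluded` attribute.
#'
#' @param event_obs Observation table restricted to one project-event (see
#'   [event_observations()]).
#' @param identifications Identification table.
#' @param include_self Count self-identifications? Default `TRUE`.
#' @return A `bioblitz_network` object: list with `nodes` (tibble `user_id`,
#'   `role`, `n_records_observed`), `edges` (tibble `observer_id`,
#'   `identifier_id`, `weight`), and `n_identifications` (sum of weights).
#'   The tibble of excluded identifications is attached as attribute
#'   `"excluded"`.
#' @export
build_network <- function(event_obs, identifications, include_self = TRUE) {
  assert_columns(event_obs, c("observation_id", "observer_id"), "event_obs")
  assert_columns(identifications, c("identification_id", "observation_id",
                                    "identifier_id"), "identifications")
  obs_key <- dplyr::select(event_obs, "observation_id", "observer_id")
  joined <- dplyr::inner_join(identifications, obs_key,
                              by = "observation_id")
  excluded <- identifications[
    !(identifications$observation_id %in% obs_key$observation_id), ,
    drop = FALSE]
  if (!include_self) {
    joined <- joined[joined$identifier_id != joined$observer_id, ,
                     drop = FALSE]
  }
  edges <- joined |>
    dplyr::count(.data$observer_id, .data$identifier_id, name = "weight") |>
    dplyr::arrange(.data$observer_id, .data$identifier_id)

  obs_counts <- event_obs |>
    dplyr::count(user_id = .data$observer_id, name = "n_records_observed")
  observers <- obs_counts$user_id
  identifiers <- unique(joined$identifier_id)
  nodes <- tibble::tibble(user_id = union(observers, identifiers)) |>
    dplyr::left_join(obs_counts, by = "user_id") |>
    dplyr::mutate(
      n_records_observed = as.integer(
        tidyr::replace_na(.data$n_records_observed, 0L)),
      role = factor(dplyr::case_when(
        .data$user_id %in% observers & .data$user_id %in% identifiers ~
          "both",
        .data$user_id %in% observers ~ "observer",
        TRUE ~ "identifier"
      ), levels = c("observer", "identifier", "both"))) |>
    dplyr::select("user_id", "role", "n_records_observed") |>
    dplyr::arrange(.data$user_id)

  structure(
    list(nodes = nodes, edges = edges,
         n_identifications = sum(edges$weight)),
    class = "bioblitz_network",
    excluded = excluded
  )
}

#' Per-user degree table of an observer-identifier network
#'
#' For each node: its role, the number of identifications it made on event
#' records (the quantity node sizes are proportional to in the usual network
#' figure), and the number of event records it observed. Sorted by
#' decreasing identifications made, ties broken by user id.
#'
#' @param g A `bioblitz_network` from [build_network()].
#' @return A tibble (`user_id`, `role`, `n_identifications_made`,
#'   `n_records_observed`).
#' @export
degree_table <- function(g) {
  stopifnot(inherits(g, "bioblitz_network"))
  made <- g$edges |>
    dplyr::group_by(user_id = .data$identifier_id) |>
    dplyr::summarise(n_identifications_made = sum(.data$weight),
                     .groups = "drop")
  g$nodes |>
    dplyr::left_join(made, by = "user_id") |>
    dplyr::mutate(n_identifications_made = as.integer(
      tidyr::replace_na(.data$n_identifications_made, 0L))) |>
    dplyr::select("user_id", "role", "n_identifications_made",
                  "n_records_observed") |>
    dplyr::arrange(dplyr::desc(.data$n_identifications_made),
                   .data$user_id)
}

#' Convert to an igraph object
#'
#' Directed edges run observer -> identifier with a `weight` attribute;
#' nodes carry `role` and `n_records_observed`. Self-identifications become
#' self-loops.
#'
#' @param g A `bioblitz_network`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "bioblitz_network"))
  igraph::graph_from_data_frame(
    d = g$edges, directed = TRUE,
    vertices = as.data.frame(g$nodes))
}

#' Export a network as GraphML
#'
#' Writes the network in GraphML for external visualization tools (Gephi,
#' Cytoscape).
#'
#' @param g A `bioblitz_network`.
#' @param path Output file path.
#' @return Invisibly, `g`.
#' @export
write_graphml <- function(g, path) {
  ig <- as_igraph(g)
  # igraph refuses non-standard attribute classes; role as character
  igraph::V(ig)$role <- as.character(igraph::V(ig)$role)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(g)
}

#' @export
print.bioblitz_network <- function(x, ...) {
  tab <- table(x$nodes$role)
  cat("Observer-identifier network\n")
  cat(sprintf("  %d nodes (%d observer, %d identifier, %d both), %d edges, %d identifications\n",
              nrow(x$nodes), tab[["observer"]], tab[["identifier"]],
              tab[["both"]], nrow(x$edges), x$n_identifications))
  invisible(x)
}

#' Plot the degree structure of an observer-identifier network
#'
#' @param object A `bioblitz_network`.
#' @param ... Unused.
#' @return A ggplot of identifications made per user, coloured by role.
#' @method autoplot bioblitz_network
#' @export
autoplot.bioblitz_network <- function(object, ...) {
  dt <- degree_table(object)
  dt$rank <- seq_len(nrow(dt))
  ggplot2::ggplot(dt, ggplot2::aes(x = .data$rank,
                                   y = .data$n_identifications_made,
                                   colour = .data$role)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(observer = "black",
                                            identifier = "#2c7fb8",
                                            both = "#ff7f00")) +
    ggplot2::labs(x = "User rank", y = "Identifications made",
                  colour = "Role",
                  title = "Identification effort across the event community") +
    ggplot2::theme_minimal()
}
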