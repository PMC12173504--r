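# shared fixtures built in code

# one triangle {0,1,2} plus its three projected pair edges: the smallest
# structure where every node plays both orders (k_pair = 2, k_tri = 1)
toy_simplex <- function() {
  hypergraph(3, rbind(c(0, 1), c(0, 2), c(1, 2)), rbind(c(0, 1, 2)))
}

# degenerate scheme where every game pays the same to every player, so all
# total payoffs are equal and the Fermi probability is exactly 1/2
flat_scheme <- function(value = 1) {
  structure(list(T_pair = value, R_pair = value, P_pair = value,
                 S_pair = value, T_tri = value, R_tri = value,
                 P_tri = value, S_tri = value, G_tri = value,
                 W_tri = value, alpha = 0),
            class = "payoff_scheme")
}

# state constructors from 0/1 vectors
vec_state <- function(pair, tri) strategy_state(pair = pair, tri = tri)

# binomial 99% CI half-width for a frequency estimate
binom_ci99 <- function(p, n) 2.576 * sqrt(p * (1 - p) / n)
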