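# divpart

Partitioning temporal change in metacommunity diversity into multiscale
selection, transmission, and immigration.

## The problem

Ecologists tracking a metacommunity — local communities nested in habitats,
censused repeatedly — want to know *why* diversity changed between surveys,
not just by how much. Did one species out-reproduce the others everywhere
(species-scale selection)? Did individuals in some habitats do better than
conspecifics elsewhere (habitat-scale selection)? Did single communities
diverge within a habitat (community-scale selection)? Did new species pour
in from outside (immigration)? Or did relative abundances shift so fast that
diversity responded nonlinearly (transmission)?

`divpart` answers this with an exact additive decomposition of the change in
each Shannon diversity component. With counts `n_ijk` for species *i*,
habitat *j*, community *k*, relative abundances factor by the chain rule

```
p_ijk = p_i.. * p_{j|i.} * p_{k|ij}
```

and each diversity component is an average of per-individual rarity scores,
`H_o = Σ p_ijk z_ijko` with `z_γ = −log p_i..`, `z_α = −log p_{i|jk}`,
`z_β = z_γ − z_α` (so `H_γ = H_α + H_β`, and `H_β` is the mutual information
between species identity and location). The census-to-census change splits
exactly as

```
ΔH_o = species selection + habitat selection + community selection
       + transmission + immigration
```

where the three selection terms track changes in `p_i..`, `p_{j|i.}` and
`p_{k|ij}` among *residents* (individuals of species already recorded in
their community), transmission tracks the change in the scores `z`
themselves, and immigration carries the contribution of individuals of
species newly observed in a community, weighted by the immigrant fraction φ.
Exponentiating converts every additive term to a multiplicative factor on
the Hill-number scale (`exp(H)` = effective number of equally abundant
species). Gamma diversity ignores where individuals of a species live, so
its habitat and community selection terms are identically zero.

A Poisson parametric bootstrap (future counts resampled with means equal to
the observed present counts; 1000 replicates and empirical 95% intervals by
default) attaches drift-only uncertainty to every term, and a synthetic
metacommunity simulator with scale-specific fitness multipliers and
scheduled immigration pulses provides controlled truth for validation.

## Worked example

Two species in four mesocosm communities nested in two habitat types,
censused in May and June; the aphid booms in the grass habitat:

```r
library(divpart)
map  <- community_map(c("m1","m2","m3","m4"), c("grass","grass","shrub","shrub"))
prev <- count_table(matrix(c(12,30, 20,25, 8,40, 16,35), 2, 4,
        dimnames=list(c("aphid","moth"), c("m1","m2","m3","m4"))), map, time="may")
fut  <- count_table(matrix(c(48,28, 60,24, 2,42, 10,38), 2, 4,
        dimnames=list(c("aphid","moth"), c("m1","m2","m3","m4"))), map, time="june")
shannon(prev)
#>   component entropy hill
#> 1     gamma  0.6118 1.84
#> 2     alpha  0.5881 1.80
#> 3      beta  0.0236 1.02
partition_change(prev, fut)[, 1:10]
#>  from   to component species_selection habitat_selection community_selection
#>   may june     gamma            0.1475           1.1e-16             7.5e-18
#>   may june     alpha            0.1396          -6.4e-02             9.0e-03
#>   may june      beta            0.0079           6.4e-02            -9.0e-03
#>  transmission immigration total phi
#>        -0.067           0  0.08   0
#>        -0.145           0 -0.06   0
#>         0.078           0  0.14   0
```

Reading the alpha row: the initially rarer aphid gained region-wide
(species selection +0.14 nats), its uneven success across habitats pushed
local communities apart (habitat selection −0.064 nats of alpha, mirrored
as +0.064 of beta), and transmission (−0.145) absorbed the nonlinearity of
the rapid shift — the classic signature of an outbreak, where strong
selection produces little net diversity change. No cell went from absent to
present, so φ = 0 and immigration is exactly zero. Within each component
the five terms sum to `total` to machine precision.

Attach bootstrap drift intervals and run a whole series:

```r
bootstrap_partition(prev, n_reps = 1000, level = 0.95, seed = 1)
mc <- simulate_metacommunity(scenario_library()$irruption)
partition_series(mc)
```

## Command line

```sh
Rscript inst/cli/divpart simulate  --config config.json --output counts.csv
Rscript inst/cli/divpart diversity --input counts.csv --output div.csv
Rscript inst/cli/divpart partition --input counts.csv --output part.csv --json part.json
Rscript inst/cli/divpart bootstrap --input counts.csv --output boot.csv --reps 1000 --level 0.95 --seed 1
```

Counts travel as tidy long CSV/TSV (`time,species,habitat,community,count`;
zero rows optional). Every run logs its parameters, seed and package
version to standard error; errors exit nonzero.

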