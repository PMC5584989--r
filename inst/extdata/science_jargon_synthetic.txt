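abstract
accordingly
accumulation
accurate
acquisition
activation
additionally
adjacent
aggregate
algorithm
alteration
ambiguous
analog
analysis
analytical
anomalous
apparatus
approach
approximately
arbitrary
assay
assess
assessment
association
assumption
asymmetric
attenuate
attribute
baseline
bias
binding
biomarker
calibration
candidate
capacity
causal
characterization
characterize
cluster
coefficient
cohort
colleague
combination
comparable
comparison
compelling
component
composite
comprehensive
comprise
computational
concentration
conclusion
concomitant
configuration
confirm
confound
consecutive
consensus
consequently
consistent
constitute
constraint
context
contribute
contribution
control
convergence
correlate
correlation
corresponding
criterion
critical
crucial
cumulative
dataset
decrease
demonstrate
dependent
derivation
derive
designate
detectable
detection
determinant
deviation
differential
dimension
discrepancy
distinct
distribution
diverse
domain
dominant
dynamic
elevated
elucidate
emerge
empirical
endogenous
enhance
enrichment
ensure
equilibrium
equivalent
essential
establish
estimate
evaluate
evaluation
evidence
exhibit
exogenous
experimental
explicit
exposure
expression
facilitate
feasible
framework
frequency
fundamental
furthermore
generate
gradient
heterogeneity
heterogeneous
hierarchical
homogeneous
hypothesis
hypothesize
identical
identification
implement
implication
implicit
incidence
incorporate
incubation
independent
indicate
indicator
inhibition
inhibitor
initial
initiate
integrate
interaction
intermediate
interpretation
interval
intervention
intrinsic
investigate
investigation
iteration
latent
likewise
limitation
linear
localization
magnitude
mechanism
mediate
methodology
metric
modality
moderate
modification
modulate
molecular
monitor
moreover
morphology
multiple
mutation
namely
nevertheless
nonetheless
normalization
notably
novel
objective
observation
obtain
optimal
optimize
outcome
overall
paradigm
parameter
partial
participant
pathway
perturbation
phenomenon
phenotype
plausible
population
potent
precise
precursor
predominant
preliminary
prevalence
previously
primarily
procedure
profile
prominent
propagation
proportion
protocol
putative
qualitative
quantify
quantitative
random
ratio
receptor
reduction
redundant
regime
region
regression
regulate
regulation
relevant
reliability
replicate
replication
represent
respectively
response
robust
sample
saturation
scenario
secondary
segment
selective
sensitivity
sequence
significant
significantly
simulation
specificity
spectrum
spontaneous
stimulus
stochastic
strategy
stratification
subsequent
subsequently
substantial
substrate
subtle
sufficient
suggest
susceptible
synthesis
systematic
technique
temporal
tendency
theoretical
therapeutic
thereby
therefore
threshold
transient
transition
typically
ubiquitous
underlying
uniform
utilize
validate
validation
variability
variable
variance
variant
variation
whereas
widespread
yield
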