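# Experimental vs calculated (periodic PBE-D3) lattice parameters of the
# alpha- and beta-cisplatin polymorphs (triclinic, space group P-1).
polymorph,parameter,unit,expt,calc
alpha,a,angstrom,6.2424,6.2218
alpha,b,angstrom,6.5087,6.4154
alpha,c,angstrom,6.7451,6.7697
alpha,alpha,degree,69.896,69.4619
alpha,beta,degree,83.710,82.9332
alpha,gamma,degree,87.348,87.3968
beta,a,angstrom,6.2846,6.2901
beta,b,angstrom,13.4990,13.3577
beta,c,angstrom,6.6839,6.7008
beta,alpha,degree,69.444,69.918
beta,beta,degree,85.586,83.917
beta,gamma,degree,82.229,80.913
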