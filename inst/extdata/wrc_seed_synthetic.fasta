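>seed01
GKKPRNRKWRCSRVECPGQKYCERHLGTSRNRSTIPVVTQLVNH
>seed02
GWKPRGLDWGCSRDSATGYKCYERHQHRGRNRIRRPVETQLVAH
>seed03
GNKPMWRKWRCPDDSAPGWKICERHCHRCRNRPRKPVETQCVLH
>seed04
GKKPRGRKWRQSRDSAPGQKYCERCVDEERLYSRKPVETQLSAH
>seed05
GGKPRYPKWHCSRGSAPVQKLCERNVHRCRNRSYSGVETQLVPH
>seed06
GKKLRGRKWRCSHDSAPGQKYGERHVHRGRNWIRKPVENQLVIH
>seed07
GKKPRGPKWRCCRDYAPCQKYCERHNREGRAISTKPVETQLRAH
>seed08
GKIPPTRKWRCSVDSAPGQKYCERHVHRQRNASRKPVETHLVAH
>seed09
RKYPRQRKLRVGRDGFPGRKHCVRHVLRGRNNSLLPVCTQLVAN
>seed10
GKKMSKYKWRCSRDSKPGQKYCEEHVHRMRNRSRKPVTTQLVAH
>seed11
GKRYQGRKWICSQISAPGQKYCERHVHRYRMRYRKPVETQMHSH
>seed12
GKWTRGRKWRCSRDWAPGTSKCERHVHRGRNRSRRPMETQLVAH
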