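>seed01
MMSSRSPFTASQWDEKEHHDLIYKYLVAGEPVPPDE
>seed02
MMSNRAIFTASQWQELEHQALIYKYLVQGVPVKPIL
>seed03
HMSSPAPVTASRPDMLEHQAQIYSYLPEGEPVPPDL
>seed04
MMISRAPFCAMNGQELERQAHICKYLVCGVLVPWDL
>seed05
MESSRAPFDASAWLELEEQAFIYSYLVAVTPTNPDL
>seed06
MMSFIAPFTASQAVELEYQALIYKYLVRGVPVPPDI
>seed07
AMSSRASFTASQTHELECQALIYYYSVRGVPVPPDL
>seed08
MCSSRAPFTASQWQGLEHQALIYKYLDAYVPQPPHS
>seed09
MMQSRMWFQPQQMQELWHQALIWKYLVRGFPEPPDL
>seed10
MMSSRAPFTASQWQELEVQYLIYKYLVFGTIVPPVL
>seed11
MTSSRAPFTASQMQLLEHQATIYRYLVANVPVYPDL
>seed12
MMPSRAEFTASEWQELEHQALIYKYLVAGVDVPPDE
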