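region17,region5
Seoul,Metropolitan
Incheon,Metropolitan
Gyeonggi,Metropolitan
Daejeon,Chungcheong
Sejong,Chungcheong
Chungbuk,Chungcheong
Chungnam,Chungcheong
Gangwon,Gangwon
Busan,Youngnam
Daegu,Youngnam
Ulsan,Youngnam
Gyeongbuk,Youngnam
Gyeongnam,Youngnam
Gwangju,Honam
Jeonbuk,Honam
Jeonnam,Honam
Jeju,Honam
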