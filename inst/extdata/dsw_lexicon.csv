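"word_id","form","gloss","syllab","stress","verb_past","x_reads_z","slot_rules","multiword","n_syllables"
1,"muito","very","mui.to",1,FALSE,FALSE,"",FALSE,2
2,"quando","when","quan.do",1,FALSE,FALSE,"",FALSE,2
3,"disse","said","di.sse",1,FALSE,FALSE,"ss=morph",FALSE,2
4,"também","also","tam.bém",2,FALSE,FALSE,"",FALSE,2
5,"vez","time","vez",1,FALSE,FALSE,"",FALSE,1
6,"cachorro","dog","ca.cho.rro",2,FALSE,FALSE,"",FALSE,3
7,"conseguiu","got","con.se.guiu",3,TRUE,FALSE,"",FALSE,3
8,"encontrou","found","en.con.trou",3,TRUE,FALSE,"",FALSE,3
9,"gente","people","gen.te",1,FALSE,FALSE,"",FALSE,2
10,"guerra","war","gue.rra",1,FALSE,FALSE,"",FALSE,2
11,"exemplo","example","e.xem.plo",2,FALSE,TRUE,"",FALSE,3
12,"ajuda","help","a.ju.da",2,FALSE,FALSE,"",FALSE,3
13,"assim","so","a.ssim",2,FALSE,FALSE,"",FALSE,2
14,"brincar","play","brin.car",2,FALSE,FALSE,"",FALSE,2
15,"futebol","soccer","fu.te.bol",3,FALSE,FALSE,"",FALSE,3
16,"menino","boy","me.ni.no",2,FALSE,FALSE,"",FALSE,3
17,"animal","animal","a.ni.mal",3,FALSE,FALSE,"",FALSE,3
18,"carro","car","ca.rro",1,FALSE,FALSE,"",FALSE,2
19,"casa","house","ca.sa",1,FALSE,FALSE,"",FALSE,2
20,"então","then","en.tão",2,FALSE,FALSE,"",FALSE,2
21,"homem","man","ho.mem",1,FALSE,FALSE,"",FALSE,2
22,"jeito","way","jei.to",1,FALSE,FALSE,"",FALSE,2
23,"por isso","therefore","por i.sso",2,FALSE,FALSE,"",TRUE,3
24,"viajar","travel","vi.a.jar",3,FALSE,FALSE,"",FALSE,3
25,"a gente","us","a gen.te",2,FALSE,FALSE,"",TRUE,3
26,"almoço","lunch","al.mo.ço",2,FALSE,FALSE,"",FALSE,3
27,"assalto","assault","a.ssal.to",2,FALSE,FALSE,"",FALSE,3
28,"borracha","rubber","bo.rra.cha",2,FALSE,FALSE,"",FALSE,3
29,"bruxa","witch","bru.xa",1,FALSE,FALSE,"",FALSE,2
30,"cabeça","head","ca.be.ça",2,FALSE,FALSE,"",FALSE,3
31,"caiu","fell","ca.iu",2,TRUE,FALSE,"",FALSE,2
32,"começou","started","co.me.çou",3,TRUE,FALSE,"",FALSE,3
33,"de repente","suddenly","de re.pen.te",3,FALSE,FALSE,"",TRUE,4
34,"em cima","above","em ci.ma",2,FALSE,FALSE,"",TRUE,3
35,"embaixo","under","em.bai.xo",2,FALSE,FALSE,"",FALSE,3
36,"enxergar","see","en.xer.gar",3,FALSE,FALSE,"",FALSE,3
37,"escola","school","es.co.la",2,FALSE,FALSE,"",FALSE,3
38,"faz","does","faz",1,FALSE,FALSE,"",FALSE,1
39,"fazer","do","fa.zer",2,FALSE,FALSE,"",FALSE,2
40,"fez","did","fez",1,FALSE,FALSE,"",FALSE,1
41,"girafa","giraffe","gi.ra.fa",2,FALSE,FALSE,"",FALSE,3
42,"ninguém","nobody","nin.guém",2,FALSE,FALSE,"",FALSE,2
43,"pegue","take","pe.gue",1,FALSE,FALSE,"",FALSE,2
44,"porque","because","por.que",2,FALSE,FALSE,"",FALSE,2
45,"professora","teacher","pro.fe.sso.ra",3,FALSE,FALSE,"",FALSE,4
46,"quente","hot","quen.te",1,FALSE,FALSE,"",FALSE,2
47,"tenho","have","te.nho",1,FALSE,FALSE,"",FALSE,2
48,"alguém","somebody","al.guém",2,FALSE,FALSE,"",FALSE,2
49,"amanhã","tomorrow","a.ma.nhã",3,FALSE,FALSE,"",FALSE,3
50,"árvore","tree","ár.vo.re",1,FALSE,FALSE,"",FALSE,3
51,"certo","right","cer.to",1,FALSE,FALSE,"",FALSE,2
52,"correr","run","co.rrer",2,FALSE,FALSE,"",FALSE,2
53,"exame","test","e.xa.me",2,FALSE,TRUE,"",FALSE,3
54,"feliz","happy","fe.liz",2,FALSE,FALSE,"",FALSE,2
55,"presente","gift","pre.sen.te",2,FALSE,FALSE,"",FALSE,3
56,"relógio","clock","re.ló.gio",2,FALSE,FALSE,"",FALSE,3
57,"saudade","longing","sau.da.de",2,FALSE,FALSE,"",FALSE,3
58,"tempo","time","tem.po",1,FALSE,FALSE,"",FALSE,2
59,"tesoura","scissors","te.sou.ra",2,FALSE,FALSE,"",FALSE,3
60,"galinha","chicken","ga.li.nha",2,FALSE,FALSE,"",FALSE,3
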